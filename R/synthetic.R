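#' Configuration for the synthetic developmental trajectory generator
#'
#' The generator emulates the structural features the complexity method
#' exploits in real developmental scRNA-seq data. Genes are organised in
#' tiers mirroring the stages: a cell at stage s draws expression from tiers
#' t >= s, so tier-0 "core" genes are exclusive to the earliest cells while
#' the last tier is ubiquitous. Two diversity regimes are supported:
#'
#' * `"dip_early"` — the hard regime: stage-0 cells express *fewer* genes
#'   than stage-1 cells (breadth 0.3 vs 0.8) but at higher magnitude
#'   (per-stage lognormal meanlog 0.5 vs 0), concentrating on core-tier
#'   genes. Diversity is then a misleading pseudotime signal while the
#'   bipartite structure still encodes the stage order.
#' * `"monotone"` — the easy regime: equal breadth (0.8) everywhere, so the
#'   nested tier access makes expressed-gene counts fall monotonically with
#'   stage and the diversity baseline works too.
#'
#' @param n_stages Number of developmental stages. Default 4.
#' @param cells_per_stage Cells per stage. Default 50.
#' @param n_gene_tiers Number of gene tiers; defaults to `n_stages`.
#' @param genes_per_tier Genes per tier. Default 100.
#' @param nestedness Probability multiplier for expressing genes from tiers
#'   later than the cell's own stage, in \[0, 1\]. Default 0.9.
#' @param diversity_profile `"dip_early"` or `"monotone"`.
#' @param breadth Per-stage probability of expressing each accessible
#'   own-tier gene; defaults depend on the profile (see above).
#' @param stage_meanlog Per-stage lognormal location of expression weights;
#'   defaults depend on the profile.
#' @param noise_sd Lognormal scale (sdlog) of expression weights. Default 0.5.
#' @param dropout_rate Bernoulli dropout applied to generated nonzeros.
#'   Default 0.
#' @param seed Integer seed; fully determines the output.
#' @return A `trajectory_config` list.
#' @export
trajectory_config <- function(n_stages = 4, cells_per_stage = 50,
                              n_gene_tiers = n_stages, genes_per_tier = 100,
                              nestedness = 0.9,
                              diversity_profile = c("dip_early", "monotone"),
                              breadth = NULL, stage_meanlog = NULL,
                              noise_sd = 0.5, dropout_rate = 0, seed = 1) {
  diversity_profile <- match.arg(diversity_profile)
  stopifnot(n_stages >= 2, cells_per_stage >= 1, n_gene_tiers >= 2, genes_per_tier >= 1,
            nestedness >= 0, nestedness <= 1, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1)
  if (is.null(breadth)) {
    breadth <- if (diversity_profile == "dip_early") {
      c(0.3, rep(0.8, n_stages - 1))
    } else {
      rep(0.8, n_stages)
    }
  }
  if (is.null(stage_meanlog)) {
    stage_meanlog <- if (diversity_profile == "dip_early") {
      c(0.5, 0, 0.15, rep(0, n_stages - 3))[seq_len(n_stages)]
    } else {
      rep(0, n_stages)
    }
  }
  stopifnot(length(breadth) == n_stages, length(stage_meanlog) == n_stages,
            all(breadth > 0), all(breadth <= 1))
  structure(list(n_stages = n_stages, cells_per_stage = cells_per_stage,
                 n_gene_tiers = n_gene_tiers, genes_per_tier = genes_per_tier,
                 nestedness = nestedness, diversity_profile = diversity_profile,
                 breadth = breadth, stage_meanlog = stage_meanlog,
                 noise_sd = noise_sd, dropout_rate = dropout_rate, seed = seed),
            class = "trajectory_config")
}

# map a stage to its tier-access probabilities; tiers earlier than the stage
# are inaccessible, the own tier gets full breadth, later tiers get
# breadth * nestedness
tier_probs <- function(stage, cfg) {
  tier_stage <- round(seq(0, cfg$n_stages - 1, length.out = cfg$n_gene_tiers))
  p <- numeric(cfg$n_gene_tiers)
  b <- cfg$breadth[stage + 1L]
  p[tier_stage < stage] <- 0
  p[tier_stage == stage] <- b
  p[tier_stage > stage] <- b * cfg$nestedness
  rep(p, each = cfg$genes_per_tier)
}

#' Generate a synthetic developmental trajectory
#'
#' Draws a cells x genes weighted expression matrix with known stage labels
#' and gene tiers under the regime described in [trajectory_config()]:
#' Bernoulli tier-access support, lognormal positive weights, optional
#' independent dropout. The same config and seed give a bit-identical
#' matrix.
#'
#' @param config A [trajectory_config()].
#' @return A list with `matrix` (cells x genes, empty rows/columns already
#'   removed), `stages` (integer stage per cell, 0-based), `tiers` (integer
#'   tier per gene, 0-based), and `config`.
#' @export
#' @examples
#' sim <- generate_trajectory(trajectory_config(seed = 7))
#' table(sim$stages)
generate_trajectory <- function(config = trajectory_config()) {
  stopifnot(inherits(config, "trajectory_config"))
  set.seed(config$seed)
  n_c <- config$n_stages * config$cells_per_stage
  n_g <- config$n_gene_tiers * config$genes_per_tier
  stage <- rep(seq_len(config$n_stages) - 1L, each = config$cells_per_stage)
  tier <- rep(seq_len(config$n_gene_tiers) - 1L, each = config$genes_per_tier)
  m <- matrix(0, n_c, n_g,
              dimnames = list(sprintf("cell_%03d", seq_len(n_c)),
                              sprintf("gene_%03d", seq_len(n_g))))
  for (i in seq_len(n_c)) {
    p <- tier_probs(stage[i], config)
    on <- stats::runif(n_g) < p
    m[i, on] <- stats::rlnorm(sum(on), meanlog = config$stage_meanlog[stage[i] + 1L],
                              sdlog = config$noise_sd)
  }
  if (config$dropout_rate > 0) {
    nz <- which(m != 0)
    m[nz[stats::runif(length(nz)) < config$dropout_rate]] <- 0
  }
  keep_c <- rowSums(m) > 0
  keep_g <- colSums(m) > 0
  if (!any(keep_c) || !any(keep_g)) stop("configuration produced an empty matrix", call. = FALSE)
  dropped_stages <- setdiff(unique(stage), unique(stage[keep_c]))
  if (length(dropped_stages)) {
    stop("configuration produced empty stage(s): ", paste(dropped_stages, collapse = ", "),
         call. = FALSE)
  }
  list(matrix = m[keep_c, keep_g, drop = FALSE],
       stages = stage[keep_c],
       tiers = stats::setNames(tier[keep_g], colnames(m)[keep_g]),
       config = config)
}

#' Generate a pair of datasets sharing part of their gene set
#'
#' Supports the cross-dataset transfer protocol: two trajectories are drawn
#' from the same tier structure; a fraction `overlap` of each tier's genes is
#' shared between the datasets (identical tier membership, independent
#' expression draws), the rest are private to each dataset. `shift` skews the
#' second dataset's stage proportions (`p_s` proportional to
#' `exp(shift * s)`), creating population heterogeneity between the twins.
#'
#' @param config A [trajectory_config()] used for both twins.
#' @param overlap Fraction of genes shared, in (0, 1\]. Default 0.8.
#' @param shift Stage-proportion skew for twin B. Default 0.
#' @return A list with `a`, `b` (each as in [generate_trajectory()]) and
#'   `shared_genes` (character vector of ids common to both).
#' @export
generate_twin_datasets <- function(config = trajectory_config(), overlap = 0.8, shift = 0) {
  stopifnot(inherits(config, "trajectory_config"), overlap > 0, overlap <= 1)
  set.seed(config$seed)
  g_per_tier <- config$genes_per_tier
  n_shared <- round(overlap * g_per_tier)
  # shared genes sit at the start of each tier block; privates are split
  # between the twins so both see the full tier structure
  n_priv <- g_per_tier - n_shared
  n_a_priv <- ceiling(n_priv / 2)
  cfg_a <- config
  cfg_a$genes_per_tier <- n_shared + n_a_priv
  cfg_b <- config
  cfg_b$genes_per_tier <- n_shared + (n_priv - n_a_priv)
  cfg_a$seed <- config$seed
  cfg_b$seed <- config$seed + 1L
  if (shift != 0) {
    # resize twin B's stages: proportions exp(shift * s), same total cells
    total <- config$n_stages * config$cells_per_stage
    p <- exp(shift * (seq_len(config$n_stages) - 1L))
    p <- p / sum(p)
    sizes <- pmax(2L, round(p * total))
    cfg_b$stage_sizes <- sizes
  }
  a <- generate_trajectory_sized(cfg_a, prefix = "a")
  b <- generate_trajectory_sized(cfg_b, prefix = "b")
  # shared genes get a common id t<t>_shared_<j> (the first `n_shared`
  # positions of each tier block); private genes carry the twin tag. Ids are
  # derived from original column positions so post-filter survivors map right.
  relabel <- function(d, tag) {
    orig <- colnames(d$matrix)                  # gene_### within this twin
    pos_in_tier <- (as.integer(sub("gene_", "", orig)) - 1L) %% d$config$genes_per_tier + 1L
    t <- d$tiers
    ids <- ifelse(pos_in_tier <= n_shared,
                  sprintf("t%d_shared_%03d", t, pos_in_tier),
                  sprintf("t%d_%s_%03d", t, tag, pos_in_tier))
    colnames(d$matrix) <- ids
    names(d$tiers) <- ids
    rownames(d$matrix) <- paste0(tag, "_", rownames(d$matrix))
    d
  }
  a <- relabel(a, "a")
  b <- relabel(b, "b")
  list(a = a, b = b, shared_genes = intersect(colnames(a$matrix), colnames(b$matrix)))
}

# generate_trajectory with optional unequal stage sizes (internal)
generate_trajectory_sized <- function(config, prefix = "cell") {
  sizes <- config$stage_sizes
  if (is.null(sizes)) return(generate_trajectory(config))
  set.seed(config$seed)
  n_g <- config$n_gene_tiers * config$genes_per_tier
  stage <- rep(seq_len(config$n_stages) - 1L, times = sizes)
  n_c <- length(stage)
  tier <- rep(seq_len(config$n_gene_tiers) - 1L, each = config$genes_per_tier)
  m <- matrix(0, n_c, n_g,
              dimnames = list(sprintf("cell_%03d", seq_len(n_c)),
                              sprintf("gene_%03d", seq_len(n_g))))
  for (i in seq_len(n_c)) {
    p <- tier_probs(stage[i], config)
    on <- stats::runif(n_g) < p
    m[i, on] <- stats::rlnorm(sum(on), meanlog = config$stage_meanlog[stage[i] + 1L],
                              sdlog = config$noise_sd)
  }
  if (config$dropout_rate > 0) {
    nz <- which(m != 0)
    m[nz[stats::runif(length(nz)) < config$dropout_rate]] <- 0
  }
  keep_c <- rowSums(m) > 0
  keep_g <- colSums(m) > 0
  list(matrix = m[keep_c, keep_g, drop = FALSE],
       stages = stage[keep_c],
       tiers = stats::setNames(tier[keep_g], colnames(m)[keep_g]),
       config = config)
}

#' Small fixed bipartite toy matrix
#'
#' A 4-cells-by-4-genes weighted matrix with heterogeneous diversity and
#' ubiquity, handy for worked examples and unit tests: small integer weights,
#' nested support (cell_1 expresses everything, cell_4 only the ubiquitous
#' gene_4).
#'
#' @return A 4 x 4 base matrix.
#' @export
toy_bipartite_fixture <- function() {
  m <- matrix(c(
    2, 1, 3, 1,
    0, 2, 1, 2,
    0, 0, 4, 1,
    0, 0, 0, 3
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("c", 1:4), paste0("g", 1:4)))
  m
}
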