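#' Simulation configuration for paired two-species expression data
#'
#' Parameters of the latent-module generative model behind
#' [simulate_paired_expression()]. Defaults emulate a two-species tissue
#' compendium at desk scale: 500 ortholog pairs over 30 and 24 tissues with
#' 20 corresponding tissues, 8 latent co-expression modules, half of the
#' orthologs with fully diverged expression programs, mild tissue evolution
#' and multiplicative log-normal noise on an intensity scale of 1000
#' (so summarized intensities and the conventional 200 floor are meaningful).
#'
#' @param k Number of 1-1 ortholog pairs.
#' @param t_a,t_b Tissues per species.
#' @param n_common Number of corresponding tissues; the first `n_common`
#'   columns of each species correspond positionally.
#' @param m Number of latent co-expression modules (>= 1).
#' @param p_cons Fraction of orthologs with conserved expression programs.
#' @param divergence_d Loading replacement fraction in \[0, 1\] applied to
#'   diverged genes (1 = fully independent program in species B).
#' @param tissue_evolution_sd SD of the perturbation added to species-B
#'   module activities on corresponding tissues (tissues themselves evolve).
#' @param noise_sd Per-observation log-scale noise SD.
#' @param intensity_scale Positive multiplier mapping the latent scale to
#'   intensity units.
#' @param divergence_scope `"all"`: diverged genes get perturbed loadings,
#'   visible on every tissue; `"noncommon"`: divergence is injected only
#'   into species-B tissues outside the corresponding panel, so it is
#'   invisible to a corresponding-tissue analysis.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k = 500L, t_a = 30L, t_b = 24L, n_common = 20L,
                       m = 8L, p_cons = 0.5, divergence_d = 1,
                       tissue_evolution_sd = 0.2, noise_sd = 0.3,
                       intensity_scale = 1000, divergence_scope = "all",
                       seed = 7L) {
  cfg <- list(k = as.integer(k), t_a = as.integer(t_a), t_b = as.integer(t_b),
              n_common = as.integer(n_common), m = as.integer(m),
              p_cons = p_cons, divergence_d = divergence_d,
              tissue_evolution_sd = tissue_evolution_sd, noise_sd = noise_sd,
              intensity_scale = intensity_scale,
              divergence_scope = match.arg(divergence_scope,
                                           c("all", "noncommon")),
              seed = as.integer(seed))
  with(cfg, {
    if (k < 2L) stop("k must be >= 2", call. = FALSE)
    if (t_a < 3L || t_b < 3L) stop("need >= 3 tissues per species",
                                   call. = FALSE)
    if (n_common < 3L || n_common > min(t_a, t_b)) {
      stop("n_common must be in [3, min(t_a, t_b)]", call. = FALSE)
    }
    if (m < 1L) stop("m must be >= 1", call. = FALSE)
    if (p_cons < 0 || p_cons > 1) stop("p_cons must be in [0, 1]",
                                       call. = FALSE)
    if (divergence_d < 0 || divergence_d > 1) {
      stop("divergence_d must be in [0, 1]", call. = FALSE)
    }
    if (tissue_evolution_sd < 0 || noise_sd < 0) {
      stop("noise standard deviations must be >= 0", call. = FALSE)
    }
    if (intensity_scale <= 0) stop("intensity_scale must be > 0",
                                   call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate paired two-species expression data with known conservation
#'
#' Latent-module generative model. Module activities over tissues are
#' standard normal; species B inherits A's activities on corresponding
#' tissues up to a `tissue_evolution_sd` perturbation, with fresh activities
#' on its species-specific tissues. Every gene loads on the `m` modules
#' (standard-normal loadings), giving the co-expression structure the
#' reference-set methods require. Conserved genes keep identical loadings in
#' both species; diverged genes have a `divergence_d` fraction of their
#' species-B program replaced by a fresh one (or, with
#' `divergence_scope = "noncommon"`, have their species-B signal perturbed
#' only on non-corresponding tissues). Intensities are
#' `exp(signal + noise)`: strictly positive, skewed, log-normal
#' multiplicative noise, resembling summarized microarray output. Each
#' array (tissue column) is then globally scaled to a common target
#' intensity (trimmed mean = `intensity_scale`), the normalization step of
#' MAS 5.0-style summarization; this removes shared array effects that
#' would otherwise make randomly paired genes correlate positively.
#'
#' Gene identifiers are `gA0001...`/`gB0001...`; corresponding tissues are
#' labelled `ct01...` in both species and species-specific tissues
#' `sa01...`/`sb01...`.
#'
#' @param config A [sim_config()].
#' @return List with `paired` (a `paired_expression`), `truth` (class
#'   `sim_truth`: `conserved` flags, loadings, module activities) and
#'   `config`.
#' @export
simulate_paired_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  out <- with_seed(cf$seed, {
    act_a <- matrix(stats::rnorm(cf$m * cf$t_a), cf$m, cf$t_a)
    act_b <- matrix(stats::rnorm(cf$m * cf$t_b), cf$m, cf$t_b)
    cc <- seq_len(cf$n_common)
    act_b[, cc] <- act_a[, cc] +
      matrix(stats::rnorm(cf$m * cf$n_common, sd = cf$tissue_evolution_sd),
             cf$m, cf$n_common)
    load_a <- matrix(stats::rnorm(cf$k * cf$m), cf$k, cf$m)
    conserved <- rep(FALSE, cf$k)
    conserved[sample.int(cf$k, round(cf$p_cons * cf$k))] <- TRUE
    div <- which(!conserved)
    load_b <- load_a
    if (cf$divergence_scope == "all" && length(div)) {
      fresh <- matrix(stats::rnorm(length(div) * cf$m), length(div), cf$m)
      load_b[div, ] <- (1 - cf$divergence_d) * load_a[div, , drop = FALSE] +
        cf$divergence_d * fresh
    }
    sig_a <- load_a %*% act_a
    sig_b <- load_b %*% act_b
    if (cf$divergence_scope == "noncommon" && length(div) &&
        cf$t_b > cf$n_common) {
      nc <- (cf$n_common + 1L):cf$t_b
      # replacement signal matched to the marginal sd of a module signal
      fresh <- matrix(stats::rnorm(length(div) * length(nc),
                                   sd = sqrt(cf$m)),
                      length(div), length(nc))
      sig_b[div, nc] <- (1 - cf$divergence_d) * sig_b[div, nc, drop = FALSE] +
        cf$divergence_d * fresh
    }
    e_a <- exp(sig_a + matrix(stats::rnorm(cf$k * cf$t_a, sd = cf$noise_sd),
                              cf$k, cf$t_a))
    e_b <- exp(sig_b + matrix(stats::rnorm(cf$k * cf$t_b, sd = cf$noise_sd),
                              cf$k, cf$t_b))
    # MAS 5.0-style global scaling: each array (tissue column) is scaled to
    # a common target intensity (trimmed mean = intensity_scale). Without
    # it, tissues with extreme module activities would have elevated
    # intensities for all genes, a shared array effect that summarized
    # microarray data does not carry.
    scale_arrays <- function(e) {
      tm <- apply(e, 2L, mean, trim = 0.02)
      sweep(e, 2L, cf$intensity_scale / tm, `*`)
    }
    e_a <- scale_arrays(e_a)
    e_b <- scale_arrays(e_b)
    list(e_a = e_a, e_b = e_b, conserved = conserved,
         load_a = load_a, load_b = load_b, act_a = act_a, act_b = act_b)
  })
  ids_a <- sprintf("gA%04d", seq_len(cf$k))
  ids_b <- sprintf("gB%04d", seq_len(cf$k))
  tiss <- function(n_common, total, prefix) {
    c(sprintf("ct%02d", seq_len(n_common)),
      if (total > n_common) sprintf("%s%02d", prefix,
                                    seq_len(total - n_common)))
  }
  dimnames(out$e_a) <- list(ids_a, tiss(cf$n_common, cf$t_a, "sa"))
  dimnames(out$e_b) <- list(ids_b, tiss(cf$n_common, cf$t_b, "sb"))
  pairs <- data.frame(gene_a = ids_a, gene_b = ids_b,
                      stringsAsFactors = FALSE)
  truth <- structure(
    list(conserved = out$conserved,
         loading_A = out$load_a, loading_B = out$load_b,
         module_activity_A = out$act_a, module_activity_B = out$act_b),
    class = "sim_truth"
  )
  list(paired = paired_expression(out$e_a, out$e_b, pairs),
       truth = truth, config = cf)
}

#' Common-tissue labels of a simulated data set
#'
#' @param config A `sim_config`.
#' @return Character vector of the corresponding-tissue labels (identical in
#'   both species by construction).
#' @export
sim_common_tissues <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sprintf("ct%02d", seq_len(config$n_common))
}

#' Write a simulated data set as plain tab-delimited files
#'
#' Writes `A.tsv`, `B.tsv` (expression tables), `map.tsv` (ortholog pairs),
#' `common.tsv` (corresponding-tissue table) and `truth.tsv` (per-gene
#' conservation labels) to a directory, exercising the same file formats the
#' readers consume.
#'
#' @param sim Result of [simulate_paired_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(sim$paired$A, file.path(dir, "A.tsv"))
  write_expression_table(sim$paired$B, file.path(dir, "B.tsv"))
  utils::write.table(sim$paired$pairs, file.path(dir, "map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  common <- sim_common_tissues(sim$config)
  utils::write.table(data.frame(common, common), file.path(dir, "common.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(
    data.frame(gene_a = sim$paired$pairs$gene_a,
               gene_b = sim$paired$pairs$gene_b,
               conserved = sim$truth$conserved),
    file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Rank-based recovery of the simulated conservation labels
#'
#' Probability that a uniformly random (conserved, diverged) pair of valid
#' ECs is correctly ordered (conserved higher), ties counting 0.5 — the area
#' under the ROC curve of EC as a classifier of the simulator's truth label.
#'
#' @param ec An `ec_result` over the simulated ortholog pairs.
#' @param truth A `sim_truth` (or logical vector of conserved flags) of the
#'   same length.
#' @return AUC in \[0, 1\].
#' @export
recovery_score <- function(ec, truth) {
  stopifnot(inherits(ec, "ec_result"))
  lab <- if (inherits(truth, "sim_truth")) truth$conserved else truth
  stopifnot(is.logical(lab), length(lab) == ec$k)
  ok <- ec$valid & !is.na(ec$ec)
  lab <- lab[ok]
  v <- ec$ec[ok]
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one valid EC in each class", call. = FALSE)
  }
  r <- rank(v)      # average ranks: ties contribute 0.5
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
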