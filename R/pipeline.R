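write_tsv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulated comparison workflow
#'
#' End-to-end analysis on one simulated data set: generate paired expression
#' data, apply the expression-floor and zero-variance filters, score every
#' requested method on the orthologs (corresponding-tissue EC and distance
#' on the common tissues; co-expression ECs and distances on PCMs over all
#' conditions), identify CCN node sets across background quantiles, run the
#' random-pairing and permuted-reference null controls, and emit
#' distribution summaries, method-agreement tables, whole-data versus
#' common-tissue comparisons and label-recovery scores.
#'
#' Every stochastic stage receives a seed derived deterministically from the
#' global `seed` and the stage name, so a rerun with the same configuration
#' and seed reproduces every output file byte for byte.
#'
#' @param config A [sim_config()]; its own seed is overridden by `seed`.
#' @param out_dir Output directory; all results are tab-delimited files.
#' @param seed Global integer seed.
#' @param methods Methods to score, a subset of `"liao_zhang"`, `"dutilh"`,
#'   `"icc"`, `"essien"`.
#' @param essien_x Background quantile for the Essien reference node set.
#' @param ccn_quantiles Background quantiles at which CCN node sets are
#'   reported.
#' @param n_background Random gene pairs per species for the background
#'   correlation distributions.
#' @param floor Expression floor for [filter_low_expression()].
#' @param tol,max_iter ICC convergence parameters.
#' @return Invisibly, a list with all in-memory results (`sim`, filters,
#'   per-method `ec_result`s under `orthologs`, `random_pairs` and
#'   `permuted_reference`, `ccn` node sets, `summary`, `agreement`,
#'   `distance_agreement`, `subset_comparison`, `recovery`, `manifest`).
#' @export
run_full_comparison <- function(config = sim_config(), out_dir, seed = 1L,
                                methods = c("liao_zhang", "dutilh", "icc",
                                            "essien"),
                                essien_x = 0.975,
                                ccn_quantiles = c(0.95, 0.975, 0.99),
                                n_background = 20000L, floor = 200,
                                tol = 1e-3, max_iter = 100L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  config$seed <- stage_seed(seed, "simulate")
  sim <- simulate_paired_expression(config)
  f1 <- filter_low_expression(sim$paired, floor = floor)
  f2 <- drop_zero_variance(f1$paired)
  paired <- f2$paired
  kept <- match(paired$pairs$gene_a, sim$paired$pairs$gene_a)
  truth_kept <- sim$truth$conserved[kept]
  common <- sim_common_tissues(config)
  sub <- subset_tissues(paired, common, common)

  coexpr_methods <- intersect(methods, c("dutilh", "icc", "essien"))
  need_pcm <- length(coexpr_methods) > 0L
  orthologs <- list()
  distances <- list()
  icc_fit <- NULL
  nodes_by_q <- list()
  pcm_a <- pcm_b <- NULL

  if ("liao_zhang" %in% methods) {
    orthologs$liao_zhang <- liao_zhang_ec(sub)
    distances$liao_zhang <- liao_zhang_distance(sub)
  }
  if (need_pcm) {
    pcm_a <- pairwise_correlation_matrix(paired$A)
    pcm_b <- pairwise_correlation_matrix(paired$B)
    bg_a <- background_correlations(paired$A, n_background,
                                    seed = stage_seed(seed, "background_A"),
                                    species_tag = "A")
    bg_b <- background_correlations(paired$B, n_background,
                                    seed = stage_seed(seed, "background_B"),
                                    species_tag = "B")
    for (q in sort(unique(c(ccn_quantiles, essien_x)))) {
      nodes_by_q[[sprintf("%g", q)]] <-
        identify_ccn_nodes(pcm_a, pcm_b,
                           correlation_threshold(bg_a, q),
                           correlation_threshold(bg_b, q), q)
    }
    if ("dutilh" %in% methods) {
      orthologs$dutilh <- dutilh_ec(pcm_a, pcm_b)
      distances$dutilh <- coexpr_distance(pcm_a, pcm_b)
    }
    if ("icc" %in% methods) {
      icc_fit <- icc(pcm_a, pcm_b, tol = tol, max_iter = max_iter)
      orthologs$icc <- icc_fit$result
    }
    if ("essien" %in% methods) {
      nd <- nodes_by_q[[sprintf("%g", essien_x)]]$node_indices
      orthologs$essien <- essien_ec(pcm_a, pcm_b, nd)
      distances$essien <- coexpr_distance(pcm_a, pcm_b, nd)
    }
  }

  # null controls ------------------------------------------------------
  seed_rp <- stage_seed(seed, "random_pairs")
  random_pairs <- list()
  if ("liao_zhang" %in% methods) {
    random_pairs$liao_zhang <- random_pair_ec(sub, seed = seed_rp)
  }
  if ("dutilh" %in% methods) {
    random_pairs$dutilh <- random_pair_ec(pcm_a, pcm_b, seed = seed_rp)
  }
  if ("icc" %in% methods) {
    random_pairs$icc <- random_pair_ec(pcm_a, pcm_b, seed = seed_rp,
                                       weights = icc_fit$weights)
  }
  if ("essien" %in% methods) {
    nd <- nodes_by_q[[sprintf("%g", essien_x)]]$node_indices
    random_pairs$essien <- random_pair_ec(pcm_a, pcm_b, seed = seed_rp,
                                          node_indices = nd)
  }
  permuted <- list()
  if (need_pcm) {
    pcm_b_perm <- permute_reference_orthology(
      pcm_b, seed = stage_seed(seed, "permute_reference"))
    if ("dutilh" %in% methods) {
      permuted$dutilh <- dutilh_ec(pcm_a, pcm_b_perm)
    }
    if ("icc" %in% methods) {
      permuted$icc <- icc(pcm_a, pcm_b_perm, tol = tol,
                          max_iter = max_iter)$result
    }
    if ("essien" %in% methods) {
      nd <- nodes_by_q[[sprintf("%g", essien_x)]]$node_indices
      permuted$essien <- essien_ec(pcm_a, pcm_b_perm, nd)
    }
  }

  # summaries and agreements -------------------------------------------
  summary_df <- do.call(rbind, c(
    lapply(names(orthologs), function(mn)
      summarize_ec(orthologs[[mn]], "orthologs")),
    lapply(names(random_pairs), function(mn)
      summarize_ec(random_pairs[[mn]], "random_pairs")),
    lapply(names(permuted), function(mn) {
      s <- summarize_ec(permuted[[mn]], "permuted_reference")
      s
    })
  ))
  agree_df <- NULL
  mnames <- names(orthologs)
  if (length(mnames) >= 2L) {
    combos <- utils::combn(mnames, 2L, simplify = FALSE)
    agree_df <- do.call(rbind, lapply(combos, function(pr)
      method_agreement(orthologs[[pr[1L]]], orthologs[[pr[2L]]])))
  }
  dist_df <- NULL
  dnames <- names(distances)
  if (length(dnames) >= 2L) {
    combos <- utils::combn(dnames, 2L, simplify = FALSE)
    dist_df <- do.call(rbind, lapply(combos, function(pr)
      distance_agreement(distances[[pr[1L]]], distances[[pr[2L]]])))
  }
  subset_df <- NULL
  if (length(coexpr_methods)) {
    subset_df <- do.call(rbind, lapply(coexpr_methods, function(mn) {
      cmp <- compare_tissue_subsets(paired, common, common, method = mn,
                                    node_quantile = essien_x,
                                    n_background = n_background,
                                    seed = stage_seed(seed,
                                                      paste0("subset_", mn)),
                                    tol = tol, max_iter = max_iter)
      data.frame(method = mn,
                 mean_full = summarize_ec(cmp$full)$mean,
                 mean_common = summarize_ec(cmp$common)$mean,
                 t_statistic = cmp$t_statistic, p_value = cmp$p_value,
                 agreement_pearson = cmp$agreement$pearson_r,
                 agreement_spearman = cmp$agreement$spearman_rho,
                 stringsAsFactors = FALSE)
    }))
  }
  recovery <- vapply(orthologs, recovery_score, numeric(1),
                     truth = truth_kept)

  # outputs -------------------------------------------------------------
  write_simulation(sim, file.path(out_dir, "sim"))
  for (mn in names(orthologs)) {
    res <- orthologs[[mn]]
    if (!is.null(distances[[mn]])) res$distance <- distances[[mn]]$distance
    write_ec_result(res, file.path(out_dir, paste0("ec_", mn, ".tsv")),
                    pairs = paired$pairs)
  }
  for (mn in names(random_pairs)) {
    write_ec_result(random_pairs[[mn]],
                    file.path(out_dir, paste0("ec_random_", mn, ".tsv")))
  }
  for (mn in names(permuted)) {
    write_ec_result(permuted[[mn]],
                    file.path(out_dir, paste0("ec_permuted_", mn, ".tsv")))
  }
  for (qn in names(nodes_by_q)) {
    nd <- nodes_by_q[[qn]]
    write_tsv_precise(data.frame(node_index = nd$node_indices),
                      file.path(out_dir, paste0("ccn_nodes_q", qn, ".tsv")))
  }
  write_tsv_precise(summary_df, file.path(out_dir, "summary.tsv"))
  if (!is.null(agree_df)) {
    write_tsv_precise(agree_df, file.path(out_dir, "agreement.tsv"))
  }
  if (!is.null(dist_df)) {
    write_tsv_precise(dist_df, file.path(out_dir, "distance_agreement.tsv"))
  }
  if (!is.null(subset_df)) {
    write_tsv_precise(subset_df, file.path(out_dir, "subset_comparison.tsv"))
  }
  write_tsv_precise(
    data.frame(method = names(recovery), recovery_auc = unname(recovery)),
    file.path(out_dir, "recovery.tsv")
  )

  manifest <- c(
    sprintf("seed=%d", seed),
    sprintf("methods=%s", paste(methods, collapse = ",")),
    sprintf("k=%d", config$k), sprintf("t_a=%d", config$t_a),
    sprintf("t_b=%d", config$t_b), sprintf("n_common=%d", config$n_common),
    sprintf("m=%d", config$m), sprintf("p_cons=%s", format(config$p_cons)),
    sprintf("divergence_d=%s", format(config$divergence_d)),
    sprintf("tissue_evolution_sd=%s", format(config$tissue_evolution_sd)),
    sprintf("noise_sd=%s", format(config$noise_sd)),
    sprintf("intensity_scale=%s", format(config$intensity_scale)),
    sprintf("divergence_scope=%s", config$divergence_scope),
    sprintf("floor=%s", format(floor)),
    sprintf("n_background=%d", as.integer(n_background)),
    sprintf("essien_x=%s", format(essien_x)),
    sprintf("ccn_quantiles=%s", paste(ccn_quantiles, collapse = ",")),
    sprintf("icc_tol=%s", format(tol)),
    sprintf("icc_max_iter=%d", as.integer(max_iter)),
    sprintf("k_retained=%d", paired$k),
    sprintf("n_removed_low_expression=%d",
            f1$report$n_removed_low_expression),
    sprintf("n_removed_zero_variance=%d", f2$report$n_removed_zero_variance),
    "welch_t_test=two_sided_unequal_variance",
    "multiple_testing_correction=none"
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(sim = sim, paired = paired, truth_kept = truth_kept,
                 filter_low = f1$report, filter_zerovar = f2$report,
                 pcm_a = pcm_a, pcm_b = pcm_b,
                 orthologs = orthologs, distances = distances,
                 random_pairs = random_pairs, permuted_reference = permuted,
                 icc_fit = icc_fit, ccn = nodes_by_q,
                 summary = summary_df, agreement = agree_df,
                 distance_agreement = dist_df,
                 subset_comparison = subset_df,
                 recovery = recovery, manifest = manifest))
}
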