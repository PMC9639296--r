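#' Default analysis parameters
#'
#' Every threshold of the pipeline in one block: association significance
#' 1e-6, MAF filter 0.05, LD clumping 0.2, local/distant window 500 kb,
#' homoeolog regulation window 150 kb, hotspot scan 1 Mb / 100 kb with alpha
#' 0.01, TWAS FDR 0.05, top-3 TF extraction, 1000 permutations.
#'
#' @param ... named overrides.
#' @return list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(seed = 1L, maf_min = 0.05, threshold = 1e-6, r2_min = 0.2,
            local_window = 5e5, hgp_window = 1.5e5, hotspot_window = 1e6,
            hotspot_step = 1e5, hotspot_alpha = 0.01, n_perm = 1000,
            twas_fdr = 0.05, grn_top_k = 3L, expr_floor = 0,
            match_window = 1e5)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Read a study from a directory
#'
#' Loads the file layout written by [write_study()]. All required files are
#' checked up front; a missing file raises a named error before any
#' computation. `truth.json` is optional (user-data mode).
#'
#' @param dir study directory.
#' @return study list as from [simulate_study()] (without `cfg`; `truth`
#'   NULL when absent).
#' @export
read_study <- function(dir) {
  need <- c("genome.gff3", "genotypes.vcf", "ocr.bed", "trait.tsv",
            "similarity.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  expr_files <- sort(list.files(dir, pattern = "^expr_.*\\.tsv$",
                                full.names = TRUE))
  if (length(expr_files) < 2L) miss <- c(miss, "expr_<stage>.tsv (x2)")
  if (length(miss))
    stop("missing input file(s) in ", dir, ": ", paste(miss, collapse = ", "))
  tf_path <- file.path(dir, "tfs.txt")
  genome <- read_gff3(file.path(dir, "genome.gff3"),
                      tf_list = if (file.exists(tf_path)) tf_path else NULL)
  stage_of <- function(f) sub("^expr_(.*)\\.tsv$", "\\1", basename(f))
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- lapply(truth, as.data.frame)
  }
  list(genome = genome,
       gm = read_vcf(file.path(dir, "genotypes.vcf")),
       expr1 = read_expression_tsv(expr_files[1L], stage = stage_of(expr_files[1L])),
       expr2 = read_expression_tsv(expr_files[2L], stage = stage_of(expr_files[2L])),
       ocr = read_bed(file.path(dir, "ocr.bed"), genome),
       trait = read_tsv_table(file.path(dir, "trait.tsv")),
       similarity = read_tsv_table(file.path(dir, "similarity.tsv")),
       truth = truth)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> MAF filter -> per-stage eQTL mapping (scan, clump,
#' classify) -> stage overlap -> hotspot detection and stage comparison ->
#' piggybacking -> homoeolog analysis -> OCR enrichment -> TWAS ->
#' hotspot/TWAS enrichment -> TF ranking. When ground truth is available,
#' recovery metrics are appended. All tables are written to `out_dir`
#' together with a machine-readable `metrics.json`.
#'
#' @param input a [sim_config()] (the study is simulated), a study list from
#'   [simulate_study()]/[read_study()], or a directory path.
#' @param out_dir output directory, created if needed; NULL to skip writing.
#' @param params a [pipeline_params()] list.
#' @return list with all stage results and `metrics`.
#' @export
run_pipeline <- function(input, out_dir = NULL, params = pipeline_params()) {
  study <- if (inherits(input, "sim_config")) simulate_study(input)
    else if (is.character(input)) read_study(input)
    else input
  set.seed(.sub_seed(params$seed, 0L))
  genome <- study$genome
  gm <- filter_maf(study$gm, params$maf_min)
  if (any(is.na(gm$dosage))) gm <- impute_mean(gm)

  eq <- lapply(list(study$expr1, study$expr2), function(e)
    eqtl_map(gm, e, genome, threshold = params$threshold,
             r2_min = params$r2_min, window = params$local_window,
             expr_floor = params$expr_floor))
  so <- stage_overlap(eq[[1L]], eq[[2L]], gm, params$match_window)

  hs <- lapply(1:2, function(i)
    hotspot_detect(eq[[i]], genome, window = params$hotspot_window,
                   step = params$hotspot_step, n_perm = params$n_perm,
                   alpha = params$hotspot_alpha,
                   seed = .sub_seed(params$seed, i)))
  ho <- stage_overlap_hotspots(hs[[1L]]$hotspots, hs[[2L]]$hotspots)

  ## piggybacking (stage 1)
  lg <- local_egenes(eq[[1L]])
  census <- adjacency_census(lg, genome)
  adj_perm <- adjacency_permutation(lg, genome, n_perm = params$n_perm,
                                    seed = .sub_seed(params$seed, 3L))
  pairs_cls <- classify_pairs(lg, genome, seed = .sub_seed(params$seed, 4L))
  pc <- pair_correlations(pairs_cls, study$expr1)
  strata <- chromatin_strata(pc$pairs, eq[[1L]], study$ocr)

  ## homoeolog analysis (distant eQTLs of either stage)
  sub <- subgenome_analysis(study$similarity, rbind(eq[[1L]], eq[[2L]]),
                            study$expr1, genome, window = params$hgp_window,
                            n_perm = params$n_perm,
                            seed = .sub_seed(params$seed, 5L))

  ## OCR enrichment of stage-1 lead SNPs
  leads <- unique(eq[[1L]][, c("lead_snp", "chrom", "pos")])
  lio <- leads_in_ocr(leads, study$ocr)
  ocr_test <- ocr_permutation_test(leads, study$ocr, genome,
                                   n_perm = params$n_perm,
                                   seed = .sub_seed(params$seed, 6L))
  lead_flags <- lio$in_ocr[match(eq[[1L]]$lead_snp, leads$lead_snp)]
  r2_cmp <- tryCatch(r2_in_vs_out(eq[[1L]], lead_flags),
                     error = function(e) NULL)

  ## TWAS and hotspot enrichment
  tw <- twas(study$expr1, study$trait, fdr = params$twas_fdr)
  universe <- unique(eq[[1L]]$gene_id)
  hs_enrich <- if (nrow(hs[[1L]]$hotspots))
    hotspot_gene_enrichment(hs[[1L]]$hotspots, tw$gene_id[tw$significant],
                            universe) else hs[[1L]]$hotspots

  ## TF ranking for the hotspot with the most regulated TWAS genes
  grn <- NULL
  tf_ids <- genome$genes$gene_id[genome$genes$is_tf]
  if (nrow(hs[[1L]]$hotspots) && length(tf_ids)) {
    regs <- strsplit(hs[[1L]]$hotspots$regulated_genes, ",")
    n_twas <- vapply(regs, function(r)
      length(intersect(r, tw$gene_id[tw$significant])), 0L)
    best <- which.max(n_twas)
    targets <- intersect(regs[[best]], tw$gene_id[tw$significant])
    targets <- setdiff(targets, tf_ids)
    if (length(targets) >= 2L)
      grn <- rank_hotspot_tfs(study$expr1, tf_ids, targets,
                              hs[[1L]]$hotspots[best, ], genome,
                              k = params$grn_top_k)
  }

  metrics <- list(
    n_eqtl = vapply(eq, nrow, 0L),
    n_local = vapply(eq, function(x) sum(x$category == "local"), 0L),
    n_distant = vapply(eq, function(x) sum(x$category == "distant"), 0L),
    n_egenes = vapply(eq, function(x) length(unique(x$gene_id)), 0L),
    stage_overlap = as.list(so$summary),
    n_hotspots = vapply(hs, function(h) nrow(h$hotspots), 0L),
    hotspot_min_p = vapply(hs, function(h)
      if (nrow(h$hotspots)) min(h$hotspots$empirical_p) else NA_real_, 0),
    hotspot_overlap = as.list(ho$summary),
    adjacency_observed = adj_perm$observed,
    adjacency_p = adj_perm$p,
    pcc_by_class = as.list(tapply(pc$pairs$pcc, pc$pairs$pair_class, mean)),
    strata_tests = strata$tests,
    hgp_group_means = as.list(sub$group_means),
    feedback_ks = sub$feedback_tests,
    tf_enrichment_p = sub$tf_enrichment$p,
    ocr_observed = ocr_test$observed, ocr_null_mean = ocr_test$null_mean,
    ocr_ci = ocr_test$ci, ocr_p = ocr_test$p,
    r2_in_vs_out_p = if (is.null(r2_cmp)) NA_real_ else r2_cmp$p,
    n_twas_significant = sum(tw$significant),
    grn_headline_tf = if (is.null(grn)) NA_character_ else grn$headline_tf)

  if (!is.null(study$truth)) {
    truth <- study$truth
    rl <- recover_local_eqtls(eq[[1L]], truth, stage = 1L, params$match_window)
    rh <- recover_hotspots(hs[[1L]], truth)
    rd <- recover_hgp_direction(sub$pairs, truth)
    rs <- recover_stage_specific(so, truth, params$match_window)
    rt <- recover_trait_genes(tw, truth)
    reg_rank <- NA_real_
    if (!is.null(grn) && nrow(truth$hotspots))
      reg_rank <- grn$ranking$rank[
        match(truth$hotspots$regulator_gene[1L], grn$ranking$tf_id)]
    metrics$recovery <- list(
      local_rate = rl$rate, hotspot_called = all(rh$called),
      hotspot_p = max(rh$empirical_p), hotspot_target_recall = mean(rh$target_recall),
      hgp_direction_rate = rd$rate, stage_specific_rate = rs$rate,
      twas_recall = rt$recall, twas_fdr = rt$fdr,
      regulator_rank = reg_rank)
  }

  res <- list(eqtls = eq, stage_overlap = so, hotspots = hs,
              hotspot_overlap = ho, census = census, adjacency = adj_perm,
              pairs = pc, strata = strata, subgenome = sub,
              ocr_flags = lio$flags, ocr_test = ocr_test, r2_cmp = r2_cmp,
              twas = tw, hotspot_enrichment = hs_enrich, grn = grn,
              metrics = metrics, study = study)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

#' @noRd
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  for (i in 1:2)
    write_tsv_table(res$eqtls[[i]], p(sprintf("eqtls_stage%d.tsv", i)))
  for (i in 1:2) {
    h <- res$hotspots[[i]]$hotspots
    write_tsv_table(h, p(sprintf("hotspots_stage%d.tsv", i)))
    if (nrow(h))
      write_bed(data.frame(chrom = h$chrom, start = h$start, end = h$end,
                           name = h$hotspot_id),
                p(sprintf("hotspots_stage%d.bed", i)))
  }
  write_tsv_table(res$census, p("adjacency_census.tsv"))
  write_tsv_table(res$pairs$pairs, p("gene_pairs.tsv"))
  write_tsv_table(res$subgenome$pairs, p("hgp.tsv"))
  write_tsv_table(res$twas, p("twas.tsv"))
  write_tsv_table(res$ocr_flags, p("lead_ocr_flags.tsv"))
  if (nrow(res$hotspot_enrichment %||% data.frame()))
    write_tsv_table(res$hotspot_enrichment, p("hotspot_twas_enrichment.tsv"))
  if (!is.null(res$grn)) write_tsv_table(res$grn$ranking, p("tf_ranking.tsv"))
  jsonlite::write_json(res$metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(out_dir)
}
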