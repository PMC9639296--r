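#' Gradient-boosted regression of a target gene on TF expression
#'
#' Fits an XGBoost tree regressor of the target's `log2(TPM+1)` on the
#' `log2(TPM+1)` of every TF (the target removed from its own feature set
#' when it is a TF) and returns per-TF total-gain importances. Default
#' hyperparameters: 1000 trees of depth 3, learning rate 1e-4, L1 penalty 0,
#' L2 penalty 1. Training is single-threaded and deterministic.
#'
#' @param expr a [bn_expr].
#' @param tf_list character vector of TF gene ids (must be expression
#'   columns).
#' @param target_gene target gene id.
#' @param n_estimators,max_depth,learning_rate,reg_alpha,reg_lambda
#'   boosted-tree hyperparameters.
#' @param nthread threads for xgboost (default 1 for determinism).
#' @return named numeric vector of gain importances over all TFs (zeros for
#'   TFs never used in a split). All-zero with a warning for a constant
#'   target.
#' @export
train_target_model <- function(expr, tf_list, target_gene,
                               n_estimators = 1000, max_depth = 3,
                               learning_rate = 1e-4, reg_alpha = 0,
                               reg_lambda = 1, nthread = 1) {
  tfs <- setdiff(unique(tf_list), target_gene)
  missing <- setdiff(c(tfs, target_gene), expr$gene_ids)
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (length(expr$accessions) < 50L)
    stop("need at least 50 samples to train a target model")
  X <- log2p1(expr$tpm[, tfs, drop = FALSE])
  y <- log2p1(expr$tpm[, target_gene])
  imp <- stats::setNames(numeric(length(tfs)), tfs)
  if (stats::sd(y) == 0) {
    warning("constant target expression: all importances zero")
    return(imp)
  }
  dm <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = list(max_depth = max_depth, eta = learning_rate,
                  alpha = reg_alpha, lambda = reg_lambda,
                  objective = "reg:squarederror", nthread = nthread),
    data = dm, nrounds = n_estimators, verbose = 0)
  it <- xgboost::xgb.importance(model = booster)
  if (!is.null(it) && nrow(it)) imp[it$Feature] <- it$Gain
  imp
}

#' Top-k TFs by importance
#'
#' @param importances named numeric vector from [train_target_model()].
#' @param k how many TFs (default 3, the conventional extraction depth).
#' @return character vector of up to `k` TF ids with non-zero importance,
#'   ordered by decreasing importance, ties by lexicographic id.
#' @export
top_k_tfs <- function(importances, k = 3L) {
  nz <- importances[importances > 0]
  if (length(nz) == 0L) return(character(0))
  o <- order(-nz, names(nz))
  names(nz)[o][seq_len(min(k, length(nz)))]
}

#' Aggregate per-target top-k TF lists into a ranking
#'
#' Counts, for every TF, in how many targets it appears in the top-k
#' (`top_k_count`) and in how many it is ranked first (`first_rank_count`).
#' TFs are ranked by decreasing `top_k_count`, ties by `first_rank_count`
#' then id; tied TFs share a rank.
#'
#' @param per_target_topk list of character vectors (ordered top-k TF ids
#'   per target).
#' @return data.frame: `tf_id`, `top_k_count`, `first_rank_count`, `rank`.
#' @export
aggregate_ranking <- function(per_target_topk) {
  all_tf <- sort(unique(unlist(per_target_topk)))
  if (length(all_tf) == 0L)
    return(data.frame(tf_id = character(), top_k_count = integer(),
                      first_rank_count = integer(), rank = integer()))
  topk <- table(factor(unlist(per_target_topk), levels = all_tf))
  first <- table(factor(unlist(lapply(per_target_topk, function(x)
    if (length(x)) x[1L] else NULL)), levels = all_tf))
  out <- data.frame(tf_id = all_tf, top_k_count = as.integer(topk),
                    first_rank_count = as.integer(first))
  out <- out[order(-out$top_k_count, -out$first_rank_count, out$tf_id), ]
  key <- paste(out$top_k_count, out$first_rank_count)
  out$rank <- match(key, unique(key))
  rownames(out) <- NULL
  out
}

#' Rank candidate upstream TFs for a hotspot-regulated gene set
#'
#' Trains one boosted-tree model per target gene, extracts the top-k TFs of
#' each, aggregates the occurrence counts into a ranking and flags TFs whose
#' gene body lies inside the hotspot interval. The headline candidate is the
#' best-ranked in-hotspot TF.
#'
#' @param expr a [bn_expr].
#' @param tf_list character vector of TF gene ids.
#' @param target_genes character vector of target gene ids (e.g. TWAS
#'   significant genes regulated by the hotspot).
#' @param hotspot single-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), or NULL to skip flagging.
#' @param genome a [bn_genome].
#' @param k top-k extraction depth (default 3).
#' @param ... passed to [train_target_model()] (hyperparameter overrides).
#' @return list with `ranking` (plus `in_hotspot` flag), `headline_tf`
#'   (best-ranked in-hotspot TF or NA) and `per_target` top-k lists.
#' @export
rank_hotspot_tfs <- function(expr, tf_list, target_genes, hotspot, genome,
                             k = 3L, ...) {
  per_target <- lapply(target_genes, function(tg)
    top_k_tfs(train_target_model(expr, tf_list, tg, ...), k = k))
  names(per_target) <- target_genes
  ranking <- aggregate_ranking(per_target)
  if (!is.null(hotspot) && nrow(ranking)) {
    g <- genome$genes
    gi <- match(ranking$tf_id, g$gene_id)
    ranking$in_hotspot <- !is.na(gi) & g$chrom[gi] == hotspot$chrom[1L] &
      g$start[gi] >= hotspot$start[1L] & g$end[gi] <= hotspot$end[1L]
  } else if (nrow(ranking)) {
    ranking$in_hotspot <- FALSE
  }
  head_tf <- if (nrow(ranking) && any(ranking$in_hotspot))
    ranking$tf_id[ranking$in_hotspot][1L] else NA_character_
  list(ranking = ranking, headline_tf = head_tf, per_target = per_target)
}
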