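#' Recovery of planted local eQTLs
#'
#' A planted (gene, SNP) local effect counts as recovered when the gene has
#' an eQTL classified local whose member set contains the causal SNP, or
#' whose lead lies within `match_window` bp of it on the same chromosome.
#'
#' @param eqtls classified eQTL data.frame.
#' @param truth ground truth from [simulate_expression()].
#' @param stage 1 or 2; stage-2 scoring excludes stage-1-only plantings.
#' @param match_window lead-distance tolerance in bp (default 100 kb).
#' @return list with `detail` (per planting, `recovered` flag) and `rate`.
#' @export
recover_local_eqtls <- function(eqtls, truth, stage = 1L, match_window = 1e5) {
  tl <- truth$local
  if (stage == 2L) tl <- tl[!tl$stage1_only, , drop = FALSE]
  loc <- eqtls[eqtls$category == "local", , drop = FALSE]
  tl$recovered <- vapply(seq_len(nrow(tl)), function(i) {
    d <- loc[loc$gene_id == tl$gene_id[i], , drop = FALSE]
    if (nrow(d) == 0L) return(FALSE)
    in_members <- vapply(strsplit(d$members, ","),
                         function(m) tl$snp_id[i] %in% m, logical(1))
    any(in_members | (d$chrom == tl$chrom[i] &
                        abs(d$pos - tl$pos[i]) <= match_window))
  }, logical(1))
  list(detail = tl, rate = mean(tl$recovered))
}

#' Recovery of planted hotspots
#'
#' @param hs result of [hotspot_detect()].
#' @param truth ground truth.
#' @return data.frame per planted hotspot: `called` (causal SNP inside a
#'   merged hotspot), `empirical_p` of that hotspot, `target_recall`
#'   (fraction of planted target genes among the hotspot's regulated genes).
#' @export
recover_hotspots <- function(hs, truth) {
  th <- truth$hotspots
  out <- lapply(seq_len(nrow(th)), function(i) {
    hit <- hs$hotspots[hs$hotspots$chrom == th$chrom[i] &
                         hs$hotspots$start <= th$pos[i] &
                         hs$hotspots$end > th$pos[i], , drop = FALSE]
    tg <- truth$hotspot_targets$gene_id[
      truth$hotspot_targets$hotspot_id == th$hotspot_id[i]]
    if (nrow(hit) == 0L)
      return(data.frame(hotspot_id = th$hotspot_id[i], called = FALSE,
                        empirical_p = NA_real_, target_recall = 0))
    reg <- strsplit(hit$regulated_genes[1L], ",")[[1L]]
    data.frame(hotspot_id = th$hotspot_id[i], called = TRUE,
               empirical_p = hit$empirical_p[1L],
               target_recall = mean(tg %in% reg))
  })
  do.call(rbind, out)
}

#' Recovery of planted homoeolog regulation directions
#'
#' @param pairs annotated pairs with `reg_class` (see [regulation_class()]).
#' @param truth ground truth; feedback and direct pairs have a known
#'   regulating side.
#' @return list with `detail` and `rate` (fraction of planted asymmetric
#'   pairs whose direction was recovered).
#' @export
recover_hgp_direction <- function(pairs, truth) {
  th <- truth$hgp[truth$hgp$type %in% c("feedback", "direct"), , drop = FALSE]
  key <- paste(pairs$an_gene, pairs$cn_gene)
  m <- match(paste(th$an_gene, th$cn_gene), key)
  expected <- ifelse(th$regulator == "An", "An_reg_Cn", "Cn_reg_An")
  th$recovered <- !is.na(m) & pairs$reg_class[m] == expected
  list(detail = th, rate = mean(th$recovered))
}

#' Recovery of stage-specific planted effects
#'
#' @param so output of [stage_overlap()] on the two stages' eQTLs.
#' @param truth ground truth.
#' @param match_window lead-distance tolerance in bp.
#' @return list with `rate`: fraction of stage-1-only plantings whose
#'   matching stage-1 local eQTL has status `s1_only`.
#' @export
recover_stage_specific <- function(so, truth, match_window = 1e5) {
  tl <- truth$local[truth$local$stage1_only, , drop = FALSE]
  s1 <- so$s1[so$s1$category == "local", , drop = FALSE]
  status <- vapply(seq_len(nrow(tl)), function(i) {
    d <- s1[s1$gene_id == tl$gene_id[i] & s1$chrom == tl$chrom[i] &
              abs(s1$pos - tl$pos[i]) <= match_window, , drop = FALSE]
    if (nrow(d) == 0L) return(NA_character_)
    d$status[which.min(d$lead_p)]
  }, character(1))
  list(detail = cbind(tl, status = status),
       rate = mean(status == "s1_only", na.rm = TRUE),
       n_scored = sum(!is.na(status)))
}

#' Recovery of trait-causal genes by TWAS
#'
#' @param tw TWAS result from [twas()].
#' @param truth ground truth.
#' @return list with `recall` (causal genes called significant), `n_called`,
#'   `fdr` (fraction of significant genes not planted causal).
#' @export
recover_trait_genes <- function(tw, truth) {
  causal <- truth$trait_genes$gene_id
  sig <- tw$gene_id[tw$significant]
  list(recall = mean(causal %in% sig), n_called = length(sig),
       fdr = if (length(sig)) mean(!(sig %in% causal)) else 0)
}
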