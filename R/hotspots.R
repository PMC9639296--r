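#' Sliding-window counts of distant-eQTL leads
#'
#' Windows of `window` bp every `step` bp per chromosome; the trailing
#' partial windows (clipped at the chromosome end) are included, so every
#' lead is covered by the same number of windows wherever it falls.
#'
#' @param leads data.frame of distant-eQTL lead positions (`chrom`, `pos`,
#'   0-based).
#' @param genome a [bn_genome].
#' @param window window size in bp (default 1 Mb).
#' @param step step size in bp (default 100 kb).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open, clipped),
#'   `count`.
#' @export
window_counts <- function(leads, genome, window = 1e6, step = 1e5) {
  out <- lapply(seq_len(nrow(genome$chroms)), function(ci) {
    nm <- genome$chroms$name[ci]
    len <- genome$chroms$length[ci]
    ws <- seq(0, max(0, len - 1), by = step)
    pos <- sort(leads$pos[leads$chrom == nm])
    data.frame(chrom = nm, start = ws, end = pmin(ws + window, len),
               count = .window_point_counts(pos, ws, window))
  })
  do.call(rbind, out)
}

#' Permutation null of the genome-wide maximum window count
#'
#' Each permutation drops `n_leads` positions uniformly over the concatenated
#' chromosome lengths, recomputes the sliding-window counts and records the
#' genome-wide maximum. The distribution of these maxima is the null against
#' which observed window counts are judged.
#'
#' @param n_leads number of distant-eQTL leads to place.
#' @param genome a [bn_genome].
#' @inheritParams window_counts
#' @param n_perm number of permutations (default 1000; below 100 the
#'   resulting threshold is flagged as unstable).
#' @param seed optional integer; when given the RNG is seeded locally.
#' @param per_chromosome keep the observed per-chromosome lead counts instead
#'   of fully uniform placement.
#' @param leads required when `per_chromosome = TRUE`: observed leads.
#' @return integer vector of `n_perm` genome-wide maxima.
#' @export
permute_max_null <- function(n_leads, genome, window = 1e6, step = 1e5,
                             n_perm = 1000, seed = NULL,
                             per_chromosome = FALSE, leads = NULL) {
  if (n_perm < 100) warning("n_perm < 100: hotspot threshold will be unstable")
  if (!is.null(seed)) set.seed(seed)
  len <- genome$chroms$length
  nms <- genome$chroms$name
  ws_list <- lapply(len, function(L) seq(0, max(0, L - 1), by = step))
  if (per_chromosome) {
    if (is.null(leads)) stop("per_chromosome placement needs the observed leads")
    n_per <- table(factor(leads$chrom, levels = nms))
  }
  vapply(seq_len(n_perm), function(p) {
    if (per_chromosome) {
      counts <- as.integer(n_per)
    } else {
      ci <- sample.int(length(len), n_leads, replace = TRUE, prob = len)
      counts <- tabulate(ci, nbins = length(len))
    }
    m <- 0L
    for (k in seq_along(len)) {
      if (counts[k] == 0L) next
      pos <- sort(floor(runif(counts[k], 0, len[k])))
      m <- max(m, .window_point_counts(pos, ws_list[[k]], window))
    }
    as.integer(m)
  }, integer(1))
}

#' Call hotspot windows against the permutation null
#'
#' The call threshold is the smallest integer `c` such that the fraction of
#' null maxima at or above `c` is below `alpha`; windows with `count >= c`
#' are called, with `empirical_p = mean(null >= count)`.
#'
#' @param counts window counts from [window_counts()].
#' @param null_maxima from [permute_max_null()] (same window/step).
#' @param alpha significance level (default 0.01).
#' @return called windows with `empirical_p` and the threshold as attribute
#'   `"threshold"`.
#' @export
call_hotspots <- function(counts, null_maxima, alpha = 0.01) {
  cmax <- max(c(counts$count, null_maxima)) + 1L
  cc <- 0:cmax
  frac <- vapply(cc, function(x) mean(null_maxima >= x), numeric(1))
  thr <- cc[which(frac < alpha)[1L]]
  called <- counts[counts$count >= thr, , drop = FALSE]
  called$empirical_p <- vapply(called$count,
                               function(x) mean(null_maxima >= x), numeric(1))
  rownames(called) <- NULL
  attr(called, "threshold") <- thr
  called
}

#' Merge called hotspot windows into hotspots
#'
#' Overlapping or abutting called windows (gap <= `merge_gap` bp between
#' half-open intervals) are unioned into a single hotspot. The merged
#' hotspot's `eqtl_count` is the number of distant eQTLs whose lead falls
#' inside the union and `regulated_genes` the genes they regulate.
#'
#' @param called called windows from [call_hotspots()].
#' @param distant_leads data.frame of distant eQTLs with `gene_id`,
#'   `lead_snp`, `chrom`, `pos`.
#' @param null_maxima optional null maxima to attach a merged `empirical_p`
#'   (that of the merged count).
#' @param merge_gap maximum gap in bp for merging (default 0 = abutting).
#' @return data.frame of hotspots: `hotspot_id`, `chrom`, `start`, `end`,
#'   `eqtl_count`, `empirical_p`, `regulated_genes` (comma-separated),
#'   `n_genes`.
#' @export
merge_hotspots <- function(called, distant_leads, null_maxima = NULL,
                           merge_gap = 0) {
  if (nrow(called) == 0L)
    return(data.frame(hotspot_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), eqtl_count = integer(),
                      empirical_p = numeric(), regulated_genes = character(),
                      n_genes = integer()))
  merged <- list()
  for (nm in unique(called$chrom)) {
    d <- called[called$chrom == nm, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end),
                          min.gapwidth = merge_gap + 1)
    merged[[nm]] <- data.frame(chrom = nm, start = IRanges::start(ir) - 1,
                               end = IRanges::end(ir))
  }
  hs <- do.call(rbind, merged)
  hs <- hs[order(hs$chrom, hs$start), , drop = FALSE]
  info <- lapply(seq_len(nrow(hs)), function(i) {
    inside <- distant_leads$chrom == hs$chrom[i] &
      distant_leads$pos >= hs$start[i] & distant_leads$pos < hs$end[i]
    list(count = sum(inside),  # distant eQTL records with their lead inside
         genes = sort(unique(distant_leads$gene_id[inside])))
  })
  hs$eqtl_count <- vapply(info, `[[`, 0L, "count")
  hs$empirical_p <- if (is.null(null_maxima)) NA_real_ else
    vapply(hs$eqtl_count, function(x) mean(null_maxima >= x), numeric(1))
  hs$regulated_genes <- vapply(info, function(x) paste(x$genes, collapse = ","), "")
  hs$n_genes <- vapply(info, function(x) length(x$genes), 0L)
  hs$hotspot_id <- sprintf("hotspot%02d", seq_len(nrow(hs)))
  rownames(hs) <- NULL
  hs[, c("hotspot_id", "chrom", "start", "end", "eqtl_count", "empirical_p",
         "regulated_genes", "n_genes")]
}

#' Detect distant-eQTL hotspots
#'
#' Convenience wrapper: filters a classified eQTL table to distant leads,
#' computes window counts, the permutation null of the genome-wide maximum,
#' calls significant windows and merges them.
#'
#' @param eqtls classified eQTL data.frame from [eqtl_map()].
#' @param genome a [bn_genome].
#' @inheritParams permute_max_null
#' @inheritParams call_hotspots
#' @return list with `hotspots` (merged), `called` (windows), `null_maxima`,
#'   `counts` and `distant_leads`.
#' @export
hotspot_detect <- function(eqtls, genome, window = 1e6, step = 1e5,
                           n_perm = 1000, alpha = 0.01, seed = NULL) {
  # one lead per distant eQTL record: several genes regulated from the same
  # locus each contribute their lead, which is what makes a hotspot
  leads <- eqtls[eqtls$category == "distant",
                 c("gene_id", "lead_snp", "chrom", "pos"), drop = FALSE]
  counts <- window_counts(leads, genome, window, step)
  null_max <- permute_max_null(nrow(leads), genome, window, step,
                               n_perm = n_perm, seed = seed)
  called <- call_hotspots(counts, null_max, alpha = alpha)
  list(hotspots = merge_hotspots(called, leads, null_max),
       called = called, null_maxima = null_max, counts = counts,
       distant_leads = leads)
}

#' Compare hotspot sets between two stages
#'
#' Per hotspot: `overlap` when some hotspot of the other stage overlaps it
#' with reciprocal containment at least `overlap_frac` (both intervals
#' covered to that fraction by the intersection), `partial` for any lesser
#' overlap, `special` for none.
#'
#' @param h1,h2 hotspot data.frames from [merge_hotspots()].
#' @param overlap_frac reciprocal containment fraction (default 0.9).
#' @return list with `h1`, `h2` (each with `overlap_status`) and `summary`.
#' @export
stage_overlap_hotspots <- function(h1, h2, overlap_frac = 0.9) {
  status <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      same <- b[b$chrom == a$chrom[i], , drop = FALSE]
      if (nrow(same) == 0L) return("special")
      inter <- pmax(0, pmin(same$end, a$end[i]) - pmax(same$start, a$start[i]))
      if (all(inter <= 0)) return("special")
      recip <- inter / (a$end[i] - a$start[i]) >= overlap_frac &
        inter / (same$end - same$start) >= overlap_frac
      if (any(recip & inter > 0)) "overlap" else "partial"
    }, character(1))
  }
  h1$overlap_status <- if (nrow(h1)) status(h1, h2) else character(0)
  h2$overlap_status <- if (nrow(h2)) status(h2, h1) else character(0)
  list(h1 = h1, h2 = h2,
       summary = table(factor(c(h1$overlap_status, h2$overlap_status),
                              levels = c("special", "partial", "overlap"))))
}

#' Enrichment of TWAS genes among hotspot-regulated genes
#'
#' One-sided hypergeometric (upper tail) test of the 2x2 table
#' (regulated by the hotspot) x (TWAS significant) over a gene universe,
#' with BH adjustment across hotspots. An exact permutation alternative is
#' available for cross-checking (`method = "permutation"`).
#'
#' @param hotspots hotspot data.frame from [merge_hotspots()]
#'   (`regulated_genes` comma-separated).
#' @param twas_genes character vector of TWAS-significant gene ids.
#' @param universe character vector of all eGenes of the stage.
#' @param method `"hypergeometric"` (default) or `"permutation"`.
#' @param n_perm permutations for the permutation method.
#' @return `hotspots` with `n_regulated`, `n_twas_overlap`, `odds_ratio`,
#'   `enrich_p`, `enrich_q` columns.
#' @export
hotspot_gene_enrichment <- function(hotspots, twas_genes, universe,
                                    method = c("hypergeometric", "permutation"),
                                    n_perm = 1000) {
  method <- match.arg(method)
  universe <- unique(universe)
  tw <- intersect(unique(twas_genes), universe)
  m <- length(tw)
  res <- lapply(seq_len(nrow(hotspots)), function(i) {
    reg <- intersect(strsplit(hotspots$regulated_genes[i], ",")[[1L]], universe)
    k <- length(reg)
    q <- length(intersect(reg, tw))
    if (method == "hypergeometric") {
      p <- if (k == 0L || m == 0L) 1 else
        stats::phyper(q - 1, m, length(universe) - m, k, lower.tail = FALSE)
    } else {
      null_q <- vapply(seq_len(n_perm), function(j)
        length(intersect(sample(universe, k), tw)), 0L)
      p <- (1 + sum(null_q >= q)) / (n_perm + 1)
    }
    # odds ratio of the 2x2 table; 0 when the overlap is empty
    a <- q; b <- k - q; cc <- m - q; d <- length(universe) - m - k + q
    or <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(n_regulated = k, n_twas_overlap = q, odds_ratio = or, enrich_p = p)
  })
  out <- cbind(hotspots, do.call(rbind, res))
  out$enrich_q <- stats::p.adjust(out$enrich_p, method = "BH")
  out
}
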