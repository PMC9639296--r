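#' Configuration for a synthetic allotetraploid eQTL study
#'
#' Returns the demo study configuration, a list of generator parameters.
#' Defaults define the documented study conditions used by the package's
#' power and calibration analyses: 300 accessions, two chromosome pairs
#' (An/Cn) of 12 Mb carrying 100 positionally matched genes each, 300 SNPs
#' per chromosome in 150-kb LD blocks, planted local eQTLs of effect 1 on the
#' log2(TPM+1) scale, one distant-eQTL hotspot whose TF regulator propagates
#' into 30 target genes with coefficient 0.8, homoeolog pairs with feedback
#' coupling -0.8, adjacent co-expressed gene pairs, open-chromatin regions
#' covering 10% of the genome with enrichment odds 5 over causal SNPs, and a
#' quantitative trait driven by five causal genes.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_accessions = 300L,
    n_chrom_per_sub = 2L,
    chrom_len = 12e6,
    genes_per_chrom = 100L,
    gene_len = c(2000, 5000),
    tf_fraction = 0.1,
    snps_per_chrom = 300L,
    ld_block_len = 150000,
    snp_mut_prob = 0.05,
    maf_range = c(0.1, 0.5),
    # local eQTL planting
    n_local_eqtl = 20L,            # standalone local-eQTL genes
    local_beta = 1,                # |beta| on log2(TPM+1) per dosage unit
    n_adjacent_coexpressed = 25L,  # adjacent gene pairs, both with local eQTLs
    shared_factor_sd = 0.8,
    same_state_coupling = 0.5,     # extra coupling when both leads share OCR state
    # hotspot planting
    n_hotspots = 1L,
    hotspot_targets = 30L,
    distant_coef = 0.8,            # propagation of regulator expression
    # homoeolog planting
    n_hgp_feedback = 15L,          # regulating gene has a local eQTL + feedback
    feedback_strength = -0.8,
    n_hgp_direct = 15L,            # regulated without local eQTL on regulator
    n_hgp_biased = 15L,            # An-shifted pairs for the propensity sign
    bias_shift = 1,
    tf_bias_feedback = 4,          # sampling weight of TF pairs for feedback
    # open chromatin
    ocr_fraction = 0.1,
    ocr_causal_enrichment = 5,     # odds multiplier for causal SNPs in OCRs
    ocr_len = c(400, 1500),
    ocr_effect_boost = 1.5,        # local |beta| multiplier for in-OCR SNPs
    # trait
    n_trait_causal_genes = 5L,
    trait_noise_sd = 1,
    # expression noise
    noise_sd = 0.5,
    expr_base_mean = 4,
    expr_base_sd = 1,
    stage_specific_frac = 0.3,     # local effects present at stage 1 only
    stages = c("20DAF", "40DAF"))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  n_genes <- 2L * cfg$n_chrom_per_sub * cfg$genes_per_chrom
  n_pairs <- cfg$n_chrom_per_sub * cfg$genes_per_chrom
  stopifnot(cfg$n_accessions >= 10,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$ocr_fraction >= 0, cfg$ocr_fraction <= 1,
            cfg$feedback_strength <= 0, cfg$feedback_strength >= -1,
            cfg$stage_specific_frac >= 0, cfg$stage_specific_frac <= 1)
  need_pairs <- cfg$n_hgp_feedback + cfg$n_hgp_direct + cfg$n_hgp_biased
  if (need_pairs > n_pairs)
    stop("planted homoeolog pairs exceed available pairs (", n_pairs, ")")
  need_genes <- 2L * need_pairs + cfg$n_hotspots * (1L + cfg$hotspot_targets) +
    cfg$n_local_eqtl + 2L * cfg$n_adjacent_coexpressed
  if (need_genes > n_genes)
    stop("planted structure needs ", need_genes, " genes but genome has ", n_genes)
  invisible(cfg)
}

#' Simulate an allotetraploid genome
#'
#' Builds `n_chrom_per_sub` chromosome pairs named `A01/C01`, `A02/C02`, ...
#' Each pair carries positionally matched gene sets (gene j on `Ak` is the
#' homoeolog of gene j on `Ck`), so reciprocal-best-hit pairing has a known
#' truth. TF status is assigned per homoeolog pair at rate `tf_fraction`.
#' Consumes the current RNG stream; [simulate_study()] seeds it once.
#'
#' @param cfg a [sim_config()].
#' @return A [bn_genome].
#' @export
simulate_genome <- function(cfg) {
  k <- cfg$n_chrom_per_sub
  chroms <- data.frame(
    name = c(sprintf("A%02d", seq_len(k)), sprintf("C%02d", seq_len(k))),
    length = cfg$chrom_len,
    subgenome = rep(c("An", "Cn"), each = k))
  slot <- cfg$chrom_len / cfg$genes_per_chrom
  tf_pair <- matrix(runif(k * cfg$genes_per_chrom) < cfg$tf_fraction,
                    nrow = k)  # chrom pair x gene slot
  genes <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(ci) {
    nm <- chroms$name[ci]
    pair_idx <- ((ci - 1L) %% k) + 1L
    j <- seq_len(cfg$genes_per_chrom)
    start <- floor((j - 1) * slot + (0.1 + 0.7 * runif(length(j))) * slot)
    len <- floor(runif(length(j), cfg$gene_len[1], cfg$gene_len[2]))
    data.frame(gene_id = sprintf("Bn%sg%04d", nm, j),
               chrom = nm,
               strand = sample(c("+", "-"), length(j), replace = TRUE),
               start = start, end = start + len,
               is_tf = tf_pair[pair_idx, j])
  }))
  bn_genome(chroms, genes)
}

#' Homoeolog pairs implied by the simulated genome layout
#'
#' @param genome a genome from [simulate_genome()].
#' @return data.frame with `an_gene`, `cn_gene`, one row per positional pair.
#' @export
sim_homoeolog_pairs <- function(genome) {
  g <- genome$genes
  an <- g[g$chrom %in% genome$chroms$name[genome$chroms$subgenome == "An"], ]
  key_an <- paste(sub("^A", "", an$chrom), an$ordinal)
  cn <- g[g$chrom %in% genome$chroms$name[genome$chroms$subgenome == "Cn"], ]
  key_cn <- paste(sub("^C", "", cn$chrom), cn$ordinal)
  m <- match(key_an, key_cn)
  data.frame(an_gene = an$gene_id[!is.na(m)], cn_gene = cn$gene_id[m[!is.na(m)]])
}

#' Simulate LD-block genotypes
#'
#' SNP positions are uniform per chromosome; SNPs within the same
#' `ld_block_len` block are copies of a block founder dosage vector with
#' per-accession mutation probability `snp_mut_prob`, giving high intra-block
#' r-squared and near-zero inter-block r-squared. Each SNP's realized MAF is
#' kept inside `maf_range` by redrawing its mutation pattern.
#'
#' @param cfg a [sim_config()].
#' @param genome genome from [simulate_genome()].
#' @return A [bn_geno] with complete (no missing) dosages.
#' @export
simulate_genotypes <- function(cfg, genome) {
  n <- cfg$n_accessions
  lo <- cfg$maf_range[1]; hi <- cfg$maf_range[2]
  maf_of <- function(v) { p <- sum(v) / (2 * length(v)); min(p, 1 - p) }
  sim_chrom <- function(nm) {
    pos <- sort(sample.int(cfg$chrom_len, cfg$snps_per_chrom)) - 1L
    block <- pos %/% cfg$ld_block_len
    cols <- matrix(0L, n, length(pos))
    for (b in unique(block)) {
      idx <- which(block == b)
      p <- runif(1, lo, hi)
      repeat {
        founder <- rbinom(n, 2L, p)
        if (maf_of(founder) >= lo) break
      }
      for (i in idx) {
        for (try in 1:50) {
          v <- founder
          mut <- runif(n) < cfg$snp_mut_prob
          v[mut] <- rbinom(sum(mut), 2L, p)
          if (maf_of(v) >= lo) break
        }
        cols[, i] <- v
      }
    }
    list(snps = data.frame(chrom = nm, pos = pos,
                           ref = "A", alt = "G"),
         dosage = cols)
  }
  parts <- lapply(genome$chroms$name, sim_chrom)
  bn_geno(sprintf("acc%03d", seq_len(n)),
          do.call(rbind, lapply(parts, `[[`, "snps")),
          do.call(cbind, lapply(parts, `[[`, "dosage")))
}

# Nearest SNP to each gene's TSS; used to pick causal SNPs for plantings.
#' @noRd
.nearest_snp <- function(genome, gm) {
  g <- genome$genes
  out <- data.frame(gene_id = g$gene_id, snp = NA_integer_, dist = NA_real_)
  for (nm in unique(g$chrom)) {
    gi <- which(g$chrom == nm)
    si <- which(gm$snps$chrom == nm)
    if (!length(si)) next
    sp <- gm$snps$pos[si]
    for (i in gi) {
      d <- abs(sp - g$tss[i])
      j <- which.min(d)
      out$snp[i] <- si[j]
      out$dist[i] <- d[j]
    }
  }
  out
}

#' Simulate two-stage expression with planted regulatory structure
#'
#' Expression is generated directly on the log2(TPM+1) scale (per-gene base
#' level plus planted effects plus Gaussian noise) and exponentiated to TPM,
#' so that planted betas are exactly linear on the analysis scale. Plantings:
#' standalone local eQTLs; adjacent co-expressed gene pairs (both with local
#' eQTLs, sharing a latent factor, with extra coupling when their causal SNPs
#' share open-chromatin state); one regulator gene per hotspot whose cis-SNP
#' drives it and whose expression propagates into its target genes; feedback
#' homoeolog pairs (regulated copy coupled negatively to the regulating
#' copy's deviation); directly regulated homoeolog pairs without a local
#' eQTL on the regulating gene; An-shifted pairs. A `stage_specific_frac`
#' subset of local effects is present at stage 1 only; stage 2 reuses the
#' remaining genetic effects with fresh noise.
#'
#' @param cfg a [sim_config()].
#' @param genome,gm outputs of [simulate_genome()] / [simulate_genotypes()].
#' @return list with `expr1`, `expr2` ([bn_expr]) and `truth`, a ground-truth
#'   list recording every planted element (see Details in the vignette).
#' @export
simulate_expression <- function(cfg, genome, gm) {
  g <- genome$genes
  n <- cfg$n_accessions
  n_genes <- nrow(g)
  near <- .nearest_snp(genome, gm)
  eligible <- which(near$dist <= 1e5)  # causal SNP must sit near the TSS

  pairs <- sim_homoeolog_pairs(genome)
  pair_ok <- match(pairs$an_gene, g$gene_id) %in% eligible &
    match(pairs$cn_gene, g$gene_id) %in% eligible
  gene_index <- function(id) match(id, g$gene_id)

  used <- logical(n_genes)
  take_genes <- function(cand, k) {
    cand <- cand[!used[cand]]
    if (length(cand) < k) stop("not enough free genes for planting")
    sel <- sample(cand, k)
    used[sel] <<- TRUE
    sel
  }

  ## --- hotspot regulators (TFs) and their cis SNPs
  hs <- list()
  if (cfg$n_hotspots > 0) {
    tf_cand <- intersect(which(g$is_tf), eligible)
    reg <- take_genes(tf_cand, cfg$n_hotspots)
    hs <- lapply(seq_along(reg), function(h) {
      list(id = sprintf("hs%02d", h), regulator = reg[h], snp = near$snp[reg[h]])
    })
  }

  ## --- homoeolog pair plantings (feedback first, TF-biased)
  pick_pairs <- function(k, weight_tf = 1) {
    ok <- which(pair_ok &
                  !used[gene_index(pairs$an_gene)] &
                  !used[gene_index(pairs$cn_gene)])
    if (length(ok) < k) stop("not enough free homoeolog pairs")
    w <- ifelse(g$is_tf[gene_index(pairs$an_gene[ok])], weight_tf, 1)
    sel <- sample(ok, k, prob = w)
    used[gene_index(pairs$an_gene[sel])] <<- TRUE
    used[gene_index(pairs$cn_gene[sel])] <<- TRUE
    sel
  }
  fb_pairs <- pick_pairs(cfg$n_hgp_feedback, cfg$tf_bias_feedback)
  di_pairs <- pick_pairs(cfg$n_hgp_direct)
  bi_pairs <- pick_pairs(cfg$n_hgp_biased)
  reg_side <- function(k) sample(c("An", "Cn"), k, replace = TRUE)
  fb_side <- reg_side(length(fb_pairs))
  di_side <- reg_side(length(di_pairs))

  ## --- adjacent co-expressed pairs: consecutive eligible, unused genes
  adj_sel <- integer(0)
  if (cfg$n_adjacent_coexpressed > 0) {
    cand <- which(!used & seq_len(n_genes) %in% eligible)
    cand_adj <- cand[cand + 1L <= n_genes &
                       g$chrom[cand] == g$chrom[pmin(cand + 1L, n_genes)] &
                       (cand + 1L) %in% cand]
    cand_adj <- sample(cand_adj)
    for (a in cand_adj) {
      if (length(adj_sel) >= cfg$n_adjacent_coexpressed) break
      if (!used[a] && !used[a + 1L]) {
        adj_sel <- c(adj_sel, a)
        used[c(a, a + 1L)] <- TRUE
      }
    }
    if (length(adj_sel) < cfg$n_adjacent_coexpressed)
      stop("could not place ", cfg$n_adjacent_coexpressed, " adjacent pairs")
  }

  ## --- standalone local eQTL genes
  solo <- take_genes(eligible, cfg$n_local_eqtl)

  ## --- hotspot targets: any other chromosome than the regulator's
  for (h in seq_along(hs)) {
    reg_chrom <- g$chrom[hs[[h]]$regulator]
    cand <- which(!used & g$chrom != reg_chrom)
    hs[[h]]$targets <- take_genes(cand, cfg$hotspot_targets)
  }

  ## --- causal SNP registry and open-chromatin flags
  local_genes <- c(solo, adj_sel, adj_sel + 1L,
                   gene_index(ifelse(fb_side == "An",
                                     pairs$an_gene[fb_pairs],
                                     pairs$cn_gene[fb_pairs])),
                   vapply(hs, function(h) h$regulator, 0L))
  local_kind <- c(rep("standalone", length(solo)),
                  rep("adjacent", 2L * length(adj_sel)),
                  rep("feedback_reg", length(fb_pairs)),
                  rep("hotspot_reg", length(hs)))
  # direct-regulation pairs use a SNP near the regulating gene's TSS that
  # acts on the partner only (no local eQTL on the regulating gene)
  di_reg <- gene_index(ifelse(di_side == "An", pairs$an_gene[di_pairs],
                              pairs$cn_gene[di_pairs]))
  di_tgt <- gene_index(ifelse(di_side == "An", pairs$cn_gene[di_pairs],
                              pairs$an_gene[di_pairs]))
  fb_reg <- local_genes[local_kind == "feedback_reg"]
  fb_tgt <- gene_index(ifelse(fb_side == "An", pairs$cn_gene[fb_pairs],
                              pairs$an_gene[fb_pairs]))

  causal_snp <- unique(c(near$snp[local_genes], near$snp[di_reg]))
  f <- cfg$ocr_fraction
  odds <- cfg$ocr_causal_enrichment * f / max(1 - f, 1e-9)
  p_in <- odds / (1 + odds)
  is_open <- stats::setNames(runif(length(causal_snp)) < p_in,
                             as.character(causal_snp))

  ## --- assemble log2(TPM+1) values
  mu <- rnorm(n_genes, cfg$expr_base_mean, cfg$expr_base_sd)
  # homoeolog copies share their baseline level, so expression propensity is
  # null for unplanted pairs and reflects planted regulation otherwise
  mu[gene_index(pairs$cn_gene)] <- mu[gene_index(pairs$an_gene)]
  dos <- gm$dosage
  n_loc <- length(local_genes)
  beta_sign <- sample(c(-1, 1), n_loc, replace = TRUE)
  # regulator effects keep positive sign so propagation sign is known
  beta_sign[local_kind %in% c("feedback_reg", "hotspot_reg")] <- 1
  boost <- ifelse(is_open[as.character(near$snp[local_genes])],
                  cfg$ocr_effect_boost, 1)
  local_beta <- beta_sign * cfg$local_beta * boost
  s1_only <- rep(FALSE, n_loc)
  dyn <- which(local_kind %in% c("standalone", "adjacent"))
  n_dyn <- round(cfg$stage_specific_frac * length(dyn))
  if (n_dyn > 0) s1_only[sample(dyn, n_dyn)] <- TRUE

  adj_open_a <- is_open[as.character(near$snp[adj_sel])]
  adj_open_b <- is_open[as.character(near$snp[adj_sel + 1L])]
  adj_coupling <- cfg$shared_factor_sd +
    ifelse(adj_open_a == adj_open_b, cfg$same_state_coupling, 0)

  build_stage <- function(stage_idx) {
    y <- matrix(rnorm(n * n_genes, 0, cfg$noise_sd), n, n_genes)
    y <- sweep(y, 2L, mu, `+`)
    for (i in seq_len(n_loc)) {
      if (stage_idx == 2L && s1_only[i]) next
      y[, local_genes[i]] <- y[, local_genes[i]] +
        local_beta[i] * dos[, near$snp[local_genes[i]]]
    }
    for (i in seq_along(di_pairs))  # direct regulation: SNP -> partner only
      y[, di_tgt[i]] <- y[, di_tgt[i]] + cfg$distant_coef * dos[, near$snp[di_reg[i]]]
    for (i in seq_along(fb_pairs)) {  # feedback: partner tracks regulator negatively
      xr <- y[, fb_reg[i]]
      y[, fb_tgt[i]] <- y[, fb_tgt[i]] + cfg$feedback_strength * (xr - mean(xr))
    }
    for (h in hs) {                   # hotspot propagation
      dev <- y[, h$regulator] - mean(y[, h$regulator])
      for (t in h$targets) y[, t] <- y[, t] + cfg$distant_coef * dev
    }
    for (i in seq_along(adj_sel)) {   # shared latent factor of adjacent pairs
      fac <- rnorm(n)
      y[, adj_sel[i]] <- y[, adj_sel[i]] + adj_coupling[i] * fac
      y[, adj_sel[i] + 1L] <- y[, adj_sel[i] + 1L] + adj_coupling[i] * fac
    }
    for (i in seq_along(bi_pairs))    # An-biased expression shift
      y[, gene_index(pairs$an_gene[bi_pairs[i]])] <-
        y[, gene_index(pairs$an_gene[bi_pairs[i]])] + cfg$bias_shift
    y
  }
  y1 <- build_stage(1L)
  y2 <- build_stage(2L)
  to_expr <- function(y, stage)
    bn_expr(gm$accessions, g$gene_id, pmax(2^y - 1, 0), stage = stage)

  ## --- trait causal genes: hotspot targets when present, else free genes
  trait_pool <- if (length(hs)) unlist(lapply(hs, `[[`, "targets")) else which(!used)
  trait_genes <- sample(trait_pool, min(cfg$n_trait_causal_genes, length(trait_pool)))

  snp_id <- gm$snps$id
  truth <- list(
    local = data.frame(
      gene_id = g$gene_id[local_genes],
      snp_id = snp_id[near$snp[local_genes]],
      chrom = gm$snps$chrom[near$snp[local_genes]],
      pos = gm$snps$pos[near$snp[local_genes]],
      beta = local_beta, kind = local_kind, stage1_only = s1_only,
      is_open = unname(is_open[as.character(near$snp[local_genes])])),
    hotspots = data.frame(
      hotspot_id = vapply(hs, `[[`, "", "id"),
      regulator_gene = g$gene_id[vapply(hs, `[[`, 0L, "regulator")],
      snp_id = snp_id[vapply(hs, `[[`, 0L, "snp")],
      chrom = gm$snps$chrom[vapply(hs, `[[`, 0L, "snp")],
      pos = gm$snps$pos[vapply(hs, `[[`, 0L, "snp")]),
    hotspot_targets = if (length(hs)) do.call(rbind, lapply(hs, function(h)
      data.frame(hotspot_id = h$id, gene_id = g$gene_id[h$targets])))
      else data.frame(hotspot_id = character(), gene_id = character()),
    hgp = {
      hgp_block <- function(sel, type, side, snp) if (length(sel))
        data.frame(an_gene = pairs$an_gene[sel], cn_gene = pairs$cn_gene[sel],
                   type = type, regulator = side, snp_id = snp) else NULL
      rbind(
        hgp_block(fb_pairs, "feedback", fb_side, snp_id[near$snp[fb_reg]]),
        hgp_block(di_pairs, "direct", di_side, snp_id[near$snp[di_reg]]),
        hgp_block(bi_pairs, "biased", NA_character_, NA_character_)) %||%
        data.frame(an_gene = character(), cn_gene = character(),
                   type = character(), regulator = character(),
                   snp_id = character())
    },
    adjacent_pairs = data.frame(
      gene_a = g$gene_id[adj_sel], gene_b = g$gene_id[adj_sel + 1L],
      coupling = adj_coupling,
      same_state = adj_open_a == adj_open_b),
    trait_genes = data.frame(gene_id = g$gene_id[trait_genes], weight = 1),
    causal_snps = data.frame(
      snp_id = snp_id[causal_snp], chrom = gm$snps$chrom[causal_snp],
      pos = gm$snps$pos[causal_snp], is_open = unname(is_open)))

  list(expr1 = to_expr(y1, cfg$stages[1]),
       expr2 = to_expr(y2, cfg$stages[2]),
       truth = truth)
}

#' Simulate open-chromatin regions
#'
#' Background OCRs tile approximately `ocr_fraction` of each chromosome while
#' avoiding causal SNPs; causal SNPs flagged open in the ground truth then
#' receive a covering OCR. The resulting in-OCR probability of a causal SNP
#' is `odds / (1 + odds)` with `odds = enrichment * f / (1 - f)`, so
#' enrichment 1 reproduces the genomic fraction `f`.
#'
#' @param cfg a [sim_config()].
#' @param genome a [bn_genome].
#' @param truth ground truth from [simulate_expression()].
#' @return A [bn_intervals] of merged OCRs.
#' @export
simulate_ocrs <- function(cfg, genome, truth) {
  cs <- truth$causal_snps
  out <- list()
  for (ci in seq_len(nrow(genome$chroms))) {
    nm <- genome$chroms$name[ci]
    len <- genome$chroms$length[ci]
    target <- cfg$ocr_fraction * len
    mean_len <- mean(cfg$ocr_len)
    m <- ceiling(1.4 * target / mean_len)
    w <- floor(runif(m, cfg$ocr_len[1], cfg$ocr_len[2]))
    s <- floor(runif(m, 0, len - w))
    ir <- IRanges::reduce(IRanges::IRanges(s + 1L, s + w))
    # drop background intervals near any causal SNP on this chromosome
    snp_pos <- cs$pos[cs$chrom == nm]
    if (length(snp_pos)) {
      hit <- IRanges::overlapsAny(
        ir, IRanges::IRanges(snp_pos + 1L - 500L, snp_pos + 1L + 500L))
      ir <- ir[!hit]
    }
    keep <- cumsum(IRanges::width(ir)) <= target
    ir <- ir[keep]
    # covering OCRs for causal SNPs flagged open
    open_pos <- cs$pos[cs$chrom == nm & cs$is_open]
    if (length(open_pos)) {
      wl <- floor(runif(length(open_pos), cfg$ocr_len[1], cfg$ocr_len[2]))
      off <- floor(runif(length(open_pos), 1, wl - 1))
      ir <- c(ir, IRanges::IRanges(open_pos + 1L - off, width = wl))
    }
    ir <- IRanges::reduce(ir)
    if (length(ir))
      out[[nm]] <- data.frame(chrom = nm, start = IRanges::start(ir) - 1L,
                              end = IRanges::end(ir))
  }
  bn_intervals(do.call(rbind, out), genome)
}

#' Simulate a quantitative trait from causal gene expression
#'
#' `trait = sum(weight * log2(TPM+1) of causal genes) + N(0, trait_noise_sd)`.
#'
#' @param cfg a [sim_config()].
#' @param expr a [bn_expr] (the stage used for trait measurement).
#' @param truth ground truth holding `trait_genes`.
#' @return data.frame with `accession`, `trait`.
#' @export
simulate_trait <- function(cfg, expr, truth) {
  w <- truth$trait_genes
  y <- log2p1(expr$tpm[, w$gene_id, drop = FALSE])
  data.frame(accession = expr$accessions,
             trait = as.numeric(y %*% w$weight) +
               rnorm(length(expr$accessions), 0, cfg$trait_noise_sd))
}

# Similarity scores: high on true homoeolog pairs, low-scoring decoys elsewhere.
#' @noRd
.simulate_similarity <- function(genome) {
  pairs <- sim_homoeolog_pairs(genome)
  true_sc <- data.frame(an_gene = pairs$an_gene, cn_gene = pairs$cn_gene,
                        score = runif(nrow(pairs), 85, 99))
  cn_all <- genome$genes$gene_id[
    genome$genes$chrom %in% genome$chroms$name[genome$chroms$subgenome == "Cn"]]
  decoys <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cn <- sample(setdiff(cn_all, pairs$cn_gene[i]), 3L)
    data.frame(an_gene = pairs$an_gene[i], cn_gene = cn,
               score = runif(3L, 30, 70))
  }))
  rbind(true_sc, decoys)
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG once from `cfg$seed` and runs every generator stage, giving
#' full determinism: identical configs produce identical studies.
#'
#' @param cfg a [sim_config()].
#' @return list with `cfg`, `genome`, `gm`, `expr1`, `expr2`, `ocr`, `trait`,
#'   `similarity`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  genome <- simulate_genome(cfg)
  gm <- simulate_genotypes(cfg, genome)
  ex <- simulate_expression(cfg, genome, gm)
  ocr <- simulate_ocrs(cfg, genome, ex$truth)
  trait <- simulate_trait(cfg, ex$expr1, ex$truth)
  similarity <- .simulate_similarity(genome)
  list(cfg = cfg, genome = genome, gm = gm, expr1 = ex$expr1, expr2 = ex$expr2,
       ocr = ocr, trait = trait, similarity = similarity, truth = ex$truth)
}

#' Write a simulated study to disk
#'
#' Emits `genome.gff3`, `tfs.txt`, `genotypes.vcf`, `expr_<stage>.tsv`,
#' `ocr.bed`, `trait.tsv`, `similarity.tsv` and `truth.json` into `dir`.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3(study$genome, p("genome.gff3"))
  writeLines(study$genome$genes$gene_id[study$genome$genes$is_tf], p("tfs.txt"))
  write_vcf(study$gm, p("genotypes.vcf"))
  write_expression_tsv(study$expr1, p(sprintf("expr_%s.tsv", study$expr1$stage)))
  write_expression_tsv(study$expr2, p(sprintf("expr_%s.tsv", study$expr2$stage)))
  write_bed(study$ocr, p("ocr.bed"))
  write_tsv_table(study$trait, p("trait.tsv"))
  write_tsv_table(study$similarity, p("similarity.tsv"))
  jsonlite::write_json(study$truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
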