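test_that("ld_r2 matches hand-computed values and handles degenerate input", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)  # perfect negative
  # hand arithmetic: r = 1.8 / 2.8 for these vectors
  expect_equal(ld_r2(c(0, 1, 2, 1, 0), c(0, 1, 1, 2, 0)), (1.8 / 2.8)^2)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_equal(r, 0)
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("scan recovers a perfect fit and is calibrated under the null", {
  set.seed(31)
  n <- 100L
  d <- random_dosage(n, 40)
  gm <- bn_geno(sprintf("a%03d", 1:n),
                data.frame(chrom = "A01", pos = seq_len(40) * 1000L,
                           ref = "A", alt = "G"), d)
  # expression exactly equal to dosage at SNP 7 (TPM = 2^d - 1)
  ex <- bn_expr(gm$accessions, "g1", matrix(2^d[, 7] - 1, ncol = 1), "s")
  sc <- scan_gene(gm, ex, "g1")
  expect_equal(sc$r2[7], 1)
  expect_equal(sc$p[7], 1e-300)  # underflow floor

  # independent normal expression: P approximately Uniform(0,1)
  set.seed(32)
  d2 <- random_dosage(300L, 1000L)
  gm2 <- bn_geno(sprintf("a%03d", 1:300),
                 data.frame(chrom = "A01", pos = seq_len(1000L) * 100L,
                            ref = "A", alt = "G"), d2)
  ex2 <- bn_expr(gm2$accessions, "g1",
                 matrix(2^rnorm(300, 4, 1) - 1, ncol = 1), "s")
  sc2 <- scan_gene(gm2, ex2, "g1")
  expect_gt(suppressWarnings(ks.test(sc2$p, "punif"))$p.value, 0.01)

  # zero-variance expression
  ex3 <- bn_expr(gm$accessions, "g1", matrix(5, n, 1), "s")
  expect_warning(sc3 <- scan_gene(gm, ex3, "g1"), "zero expression variance")
  expect_true(all(sc3$p == 1) && all(sc3$r2 == 0))
})

test_that("a planted effect of one dosage unit is detected at 1e-6", {
  hits <- sapply(1:20, function(seed) {
    set.seed(500 + seed)
    dose <- rbinom(300, 2, runif(1, 0.1, 0.5))
    y <- 4 + dose + rnorm(300, 0, 0.5)
    r <- cor(dose, y)
    p <- 2 * pt(-abs(r) * sqrt(298 / (1 - r^2)), df = 298)
    p < 1e-6
  })
  expect_gte(mean(hits), 0.95)
})

test_that("significant_snps equals a brute-force filter", {
  expect_equal(nrow(significant_snps(data.frame(p = numeric()))), 0L)
  expect_equal(nrow(significant_snps(data.frame(p = rep(0.5, 5)))), 0L)
  set.seed(41)
  st <- data.frame(p = 10^-runif(200, 0, 9), snp = seq_len(200))
  keep <- significant_snps(st, 1e-6)
  expect_equal(keep$snp, st$snp[sapply(st$p, function(x) x <= 1e-6)])
})

test_that("greedy clumping matches the explicit-loop oracle", {
  set.seed(51)
  for (rep in 1:20) {
    n_acc <- 60L
    # 10 SNPs in 3 LD blocks: founders plus small mutations
    founders <- replicate(3, rbinom(n_acc, 2, runif(1, 0.2, 0.5)))
    block <- sample(rep(1:3, length.out = 10L))
    d <- sapply(block, function(b) {
      v <- founders[, b]
      mut <- runif(n_acc) < 0.08
      v[mut] <- rbinom(sum(mut), 2, 0.3)
      v
    })
    if (any(apply(d, 2, sd) == 0)) next
    gm <- bn_geno(sprintf("a%02d", 1:n_acc),
                  data.frame(chrom = "A01", pos = order(block) * 1e3,
                             ref = "A", alt = "G")[order(order(block)), ],
                  d)
    p <- 10^-runif(10, 6, 12)
    sig <- data.frame(gene_id = "g", snp_id = gm$snps$id,
                      chrom = gm$snps$chrom, pos = gm$snps$pos,
                      beta = 1, p = p, r2 = runif(10))
    got <- clump(sig, gm, r2_min = 0.2)
    # oracle on the same (snp order) indexing
    r2mat <- cor(gm$dosage)^2
    groups <- oracle_clump_partition(p, r2mat, 0.2)
    expect_equal(nrow(got), length(groups))
    got_members <- lapply(strsplit(got$members, ","), sort)
    oracle_members <- lapply(groups, function(g) sort(gm$snps$id[g]))
    expect_setequal(sapply(got_members, paste, collapse = "|"),
                    sapply(oracle_members, paste, collapse = "|"))
    # partition property: every significant SNP in exactly one eQTL
    expect_setequal(unlist(got_members), sig$snp_id)
    expect_equal(sum(got$n_members), nrow(sig))
    # leads pairwise r2 <= 0.2
    leads <- match(got$lead_snp, gm$snps$id)
    if (length(leads) > 1L) {
      lr <- cor(gm$dosage[, leads])^2
      expect_true(all(lr[upper.tri(lr)] <= 0.2))
    }
  }
})

test_that("local/distant classification is boundary-inclusive", {
  genome <- toy_genome(n_genes = 5, chrom_len = 2e6)
  g <- genome$genes[3, ]  # start 250000, end 253000 on A01
  mk <- function(chrom, pos) data.frame(gene_id = g$gene_id, lead_snp = "s",
                                        chrom = chrom, pos = pos)
  cls <- function(chrom, pos)
    classify_eqtl(mk(chrom, pos), genome, window = 2e5)$category
  expect_equal(cls("A01", g$start + 100), "local")      # inside gene body
  expect_equal(cls("C01", g$start + 100), "distant")    # other chromosome
  expect_equal(cls("A01", g$start - 2e5), "local")      # exactly at boundary
  expect_equal(cls("A01", g$start - 2e5 - 1), "distant")
  expect_equal(cls("A01", g$end - 1 + 2e5), "local")    # last base + window
  expect_equal(cls("A01", g$end + 2e5), "distant")
})

test_that("eqtl_map output satisfies the clumping partition invariant", {
  st <- simulate_study(test_cfg(seed = 61))
  gm <- filter_maf(st$gm, 0.05)
  eq <- eqtl_map(gm, st$expr1, st$genome)
  expect_gt(nrow(eq), 0)
  # per gene: members partition the significant set and lead P is the min
  acc <- intersect(gm$accessions, st$expr1$accessions)
  Y <- log2p1(st$expr1$tpm[acc, , drop = FALSE])
  for (gid in sample(unique(eq$gene_id), 5)) {
    sc <- scan_gene(gm, st$expr1, gid)
    sig <- sc$snp_id[sc$p <= 1e-6]
    members <- unlist(strsplit(eq$members[eq$gene_id == gid], ","))
    expect_setequal(members, sig)
    expect_equal(min(eq$lead_p[eq$gene_id == gid]), min(sc$p))
  }
})

test_that("under a global null the eQTL count matches binomial expectation", {
  set.seed(71)
  n <- 200L; n_snp <- 400L; n_gene <- 150L
  d <- random_dosage(n, n_snp)
  gm <- bn_geno(sprintf("a%03d", 1:n),
                data.frame(chrom = "A01", pos = seq_len(n_snp) * 1e4,
                           ref = "A", alt = "G"), d)
  genome <- bn_genome(data.frame(name = "A01", length = 5e6, subgenome = "An"),
                      data.frame(gene_id = sprintf("g%03d", 1:n_gene),
                                 chrom = "A01", strand = "+",
                                 start = seq_len(n_gene) * 3e4,
                                 end = seq_len(n_gene) * 3e4 + 2e3))
  ex <- bn_expr(gm$accessions, genome$genes$gene_id,
                matrix(pmax(2^rnorm(n * n_gene, 4, 1) - 1, 0), n, n_gene), "s")
  eq <- eqtl_map(gm, ex, genome, threshold = 1e-4)
  n_tests <- n_snp * n_gene
  expected <- n_tests * 1e-4
  expect_lte(nrow(eq), expected + 3 * sqrt(expected) + 1)
})

test_that("stage matching separates stable and stage-specific eQTLs", {
  mk_eq <- function(gene, chrom, pos)
    data.frame(gene_id = gene, lead_snp = paste0(chrom, ":", pos + 1),
               chrom = chrom, pos = pos, lead_p = 1e-8, lead_r2 = 0.5,
               lead_beta = 1, n_members = 1L,
               members = paste0(chrom, ":", pos + 1), category = "local")
  a <- rbind(mk_eq("g1", "A01", 1e6), mk_eq("g2", "A01", 5e6))
  # identical sets: all both
  so <- stage_overlap(a, a)
  expect_true(all(so$s1$status == "both"))
  # disjoint chromosomes: none match
  b <- rbind(mk_eq("g1", "C01", 1e6), mk_eq("g2", "C01", 5e6))
  so2 <- stage_overlap(a, b)
  expect_true(all(so2$s1$status == "s1_only"))
  expect_true(all(so2$s2$status == "s2_only"))
  # within the window, different gene never matches
  cc <- rbind(mk_eq("g3", "A01", 1e6 + 5e4))
  expect_equal(stage_overlap(a, cc)$s1$status, c("s1_only", "s1_only"))
})

test_that("planted stage-specific effects are recovered as s1_only", {
  rates <- sapply(1:5, function(seed) {
    st <- simulate_study(test_cfg(seed = 700 + seed))
    gm <- filter_maf(st$gm, 0.05)
    eq1 <- eqtl_map(gm, st$expr1, st$genome)
    eq2 <- eqtl_map(gm, st$expr2, st$genome)
    so <- stage_overlap(eq1, eq2, gm)
    recover_stage_specific(so, st$truth)$rate
  })
  expect_gte(mean(rates), 0.9)
})

test_that("TWAS pinpoints a noiseless driver and controls the null", {
  st <- simulate_study(test_cfg(seed = 81))
  g <- st$truth$trait_genes$gene_id[1]
  trait0 <- data.frame(accession = st$expr1$accessions,
                       trait = log2p1(st$expr1$tpm[, g]))
  tw <- twas(st$expr1, trait0)
  expect_equal(tw$gene_id[which.min(tw$p)], g)
  expect_true(tw$significant[tw$gene_id == g])
  expect_true(all(tw$fdr_q >= tw$p))
  # permuted trait: typically nothing significant
  set.seed(82)
  perm <- data.frame(accession = st$expr1$accessions,
                     trait = sample(st$trait$trait))
  expect_lte(sum(twas(st$expr1, perm)$significant), 2L)
})

test_that("TWAS recovers independent planted causal genes with low FDR", {
  res <- sapply(1:10, function(seed) {
    st <- simulate_study(test_cfg(seed = 900 + seed, n_hotspots = 0L,
                                  n_accessions = 300L,
                                  n_trait_causal_genes = 5L))
    r <- recover_trait_genes(twas(st$expr1, st$trait), st$truth)
    c(r$recall, r$fdr)
  })
  expect_gte(mean(res[1, ]), 0.95)
  expect_lte(mean(res[2, ]), 0.1)
})

test_that("egene_summary tallies categories per gene", {
  eq <- data.frame(gene_id = c("g1", "g1", "g2"), lead_p = c(1e-8, 1e-9, 1e-7),
                   category = c("local", "distant", "distant"))
  s <- egene_summary(eq)
  expect_equal(s$n_eqtl, c(2L, 1L))
  expect_equal(s$n_local, c(1L, 0L))
  expect_equal(local_egenes(eq), "g1")
})
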