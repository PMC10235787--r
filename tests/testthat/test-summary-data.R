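test_that("read_gwas round-trips a well-formed file and validates rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "x.tsv")
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "C", "T"),
                   other_allele = c("G", "T", "A"),
                   eaf = c(0.2, 0.4, 0.3),
                   beta = c(0.10, -0.05, 0.02),
                   se = c(0.01, 0.01, 0.02),
                   pval = c(1e-23, 5.7e-7, 0.3),
                   n = c(1e5, 1e5, 1e5))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_gwas(f, trait_id = "X")
  expect_s3_class(s, "summary_stats")
  expect_equal(nrow(s$variants), 3)
  expect_equal(s$variants$beta, df$beta)

  # row with se = 0 is dropped, with a logged count
  df_bad <- df; df_bad$se[2] <- 0
  write.table(df_bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(s2 <- read_gwas(f, trait_id = "X"), "dropped 1 of 3")
  expect_equal(s2$variants$variant_id, c("rs1", "rs3"))
  expect_equal(attr(s2, "n_dropped"), 1L)

  # shuffled column order plus a column_map gives an identical read
  df_shuf <- df[, c("pval", "other_allele", "n", "beta", "variant_id",
                    "se", "eaf", "effect_allele")]
  names(df_shuf) <- c("p_val", "a2", "N_eff", "b_hat", "marker",
                      "stderr", "freq1", "a1")
  f2 <- file.path(dir, "shuffled.csv")
  write.table(df_shuf, f2, sep = ",", quote = FALSE, row.names = FALSE)
  s3 <- read_gwas(f2, column_map = list(variant_id = "marker",
                                        effect_allele = "a1",
                                        other_allele = "a2", beta = "b_hat",
                                        se = "stderr", pval = "p_val",
                                        eaf = "freq1", n = "N_eff"),
                  trait_id = "X")
  expect_equal(s3$variants, s$variants)

  # unresolvable required column -> configuration error
  expect_error(read_gwas(f2, trait_id = "X"), class = "mr_config_error")
})

test_that("summary_stats rejects empty input and flags inconsistent p-values", {
  df <- data.frame(variant_id = "rs1", effect_allele = "A",
                   other_allele = "A", beta = 0.1, se = 0.01, pval = 0.5)
  expect_error(summary_stats(df, "X"), class = "mr_empty_input")
  df2 <- data.frame(variant_id = "rs1", effect_allele = "A",
                    other_allele = "G", beta = 0.1, se = 0.01, pval = 0.9)
  expect_warning(summary_stats(df2, "X"), class = "mr_pval_inconsistent")
})

test_that("harmonise aligns, swaps and drops according to allele letters", {
  x <- make_stats(c("rs1", "rs2", "rs3"), c(0.10, 0.20, 0.30),
                  rep(0.01, 3), ea = c("A", "A", "A"), oa = c("G", "T", "C"),
                  eaf = c(0.2, 0.3, 0.4), trait_id = "X")
  # rs1 aligned, rs2 swapped (palindromic A/T handled by letters), rs3 mismatch
  y <- make_stats(c("rs1", "rs2", "rs3"), c(0.05, 0.05, 0.05),
                  rep(0.02, 3), ea = c("A", "T", "C"), oa = c("G", "A", "T"),
                  eaf = c(0.25, 0.6, 0.5), trait_id = "Y")
  expect_message(h <- harmonise(list(x, y)), "1 variant")
  expect_equal(h$variant_ids, c("rs1", "rs2"))
  expect_equal(unname(h$beta[, "Y"]), c(0.05, -0.05))
  expect_equal(unname(h$beta[, "X"]), c(0.10, 0.20))
  expect_equal(unname(h$eaf[, "Y"]), c(0.25, 0.4))  # swapped eaf complemented

  expect_error(harmonise(list(x)), class = "mr_usage_error")
  z <- make_stats("zz9", 0.1, 0.01, trait_id = "Z")
  expect_error(harmonise(list(x, z)), class = "mr_empty_input")
})

test_that("harmonise round-trip: pre-flipping a table changes nothing", {
  set.seed(11)
  J <- 12
  ids <- sprintf("rs%02d", 1:J)
  ea <- sample(c("A", "C", "G", "T"), J, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  x <- make_stats(ids, rnorm(J, 0, 0.05), runif(J, 0.005, 0.02),
                  ea = ea, oa = oa, eaf = runif(J, 0.1, 0.9), trait_id = "X")
  y <- make_stats(ids, rnorm(J, 0, 0.05), runif(J, 0.005, 0.02),
                  ea = ea, oa = oa, eaf = runif(J, 0.1, 0.9), trait_id = "Y")
  flip <- y
  flip$variants$effect_allele <- y$variants$other_allele
  flip$variants$other_allele <- y$variants$effect_allele
  flip$variants$beta <- -y$variants$beta
  flip$variants$eaf <- 1 - y$variants$eaf
  h1 <- harmonise(list(x, y))
  h2 <- harmonise(list(x, flip))
  expect_equal(h1$beta, h2$beta)
  expect_equal(h1$eaf, h2$eaf)
})

test_that("harmonisation is idempotent and sign-consistent", {
  set.seed(21)
  J <- 10
  ids <- sprintf("rs%02d", 1:J)
  x <- make_stats(ids, rnorm(J, 0, 0.05), runif(J, 0.005, 0.02), trait_id = "X")
  y <- make_stats(ids, rnorm(J, 0, 0.05), runif(J, 0.005, 0.02), trait_id = "Y")
  h1 <- harmonise(list(x, y))
  # feed the harmonised result back through as summary_stats tables
  back <- function(h, k, src) {
    s <- src
    s$variants$beta <- unname(h$beta[, k])
    s$variants$effect_allele <- h$effect_allele
    s$variants$other_allele <- h$other_allele
    s
  }
  h2 <- harmonise(list(back(h1, 1, x), back(h1, 2, y)))
  expect_equal(h2$beta, h1$beta)

  yn <- y; yn$variants$beta <- -y$variants$beta
  hn <- harmonise(list(x, yn))
  expect_equal(unname(hn$beta[, 2]), -unname(h1$beta[, 2]))
  expect_equal(unname(hn$beta[, 1]), unname(h1$beta[, 1]))
})

test_that("select_instruments clumps greedily with deterministic tie-break", {
  # 5 mutually independent variants all kept
  s <- make_stats(sprintf("rs%d", 1:5), rep(0.1, 5), rep(0.01, 5),
                  pval = rep(1e-10, 5))
  inst <- suppressWarnings(select_instruments(s, ld = NULL))
  expect_setequal(inst$variant_id, sprintf("rs%d", 1:5))

  # dominance: of two variants in LD, the smaller p survives
  s2 <- make_stats(c("rsA", "rsB"), c(0.1, 0.1), c(0.01, 0.011),
                   pval = c(1e-10, 1e-9))
  ld <- ld_info(data.frame(id_a = "rsA", id_b = "rsB", r2 = 0.9))
  inst2 <- suppressWarnings(select_instruments(s2, ld = ld))
  expect_equal(inst2$variant_id, "rsA")

  # no variant passing the threshold is an error naming the trait
  s3 <- make_stats("rs1", 0.01, 0.01, pval = 0.3, trait_id = "TG")
  expect_error(select_instruments(s3), "TG", class = "mr_empty_instruments")
})

test_that("clumping matches the matrix-based dominance oracle on toy LD", {
  set.seed(33)
  for (rep in 1:5) {
    J <- 20
    ids <- sprintf("rs%02d", 1:J)
    pv <- 10^runif(J, -30, -8.5)
    r2mat <- matrix(0, J, J, dimnames = list(ids, ids))
    # random LD pairs, some above and some below the threshold
    for (q in 1:25) {
      ij <- sample(J, 2)
      v <- sample(c(runif(1, 0.002, 1), runif(1, 0, 0.0009)), 1)
      r2mat[ij[1], ij[2]] <- r2mat[ij[2], ij[1]] <- v
    }
    diag(r2mat) <- 1
    idx <- which(upper.tri(r2mat) & r2mat > 0, arr.ind = TRUE)
    ld <- ld_info(data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                             r2 = r2mat[idx]))
    s <- make_stats(ids, rep(0.1, J), rep(0.01, J), pval = pv)
    inst <- suppressWarnings(
      select_instruments(s, ld = ld, r2_threshold = 0.001))
    expect_true(clump_oracle_check(ids, pv, r2mat, 0.001, inst$variant_id))
    # returned set is independent at the threshold
    pairs <- t(combn(inst$variant_id, 2))
    expect_true(all(ld_r2(ld, pairs[, 1], pairs[, 2]) < 0.001))
    # deterministic
    inst_b <- suppressWarnings(
      select_instruments(s, ld = ld, r2_threshold = 0.001))
    expect_identical(inst$variant_id, inst_b$variant_id)
  }
})

test_that("pool_for_mvmr pools unions, dedups, and matches the oracle", {
  x <- make_stats(c("rs1", "rs2", "rs3"), rep(0.1, 3), rep(0.01, 3),
                  pval = c(1e-10, 1e-12, 0.5), trait_id = "X")
  m <- make_stats(c("rs2", "rs3", "rs4"), rep(0.1, 3), rep(0.01, 3),
                  pval = c(1e-9, 1e-11, 1e-8 / 2), trait_id = "M")
  pooled <- pool_for_mvmr(list(x, m))
  # union of significant: rs1, rs2 (both), rs3 (M only), rs4; each once
  expect_setequal(pooled$variant_id, c("rs1", "rs2", "rs3", "rs4"))
  expect_equal(anyDuplicated(pooled$variant_id), 0L)
  # min-p rank: rs2 min(1e-12, 1e-9) ranks first
  expect_equal(pooled$variant_id[1], "rs2")
  expect_true(pooled$sig_X[pooled$variant_id == "rs2"])
  expect_true(pooled$sig_M[pooled$variant_id == "rs2"])
  expect_false(pooled$sig_X[pooled$variant_id == "rs4"])

  # with LD: pooled-then-clumped equals the dominance oracle on min-p ranks
  ld <- ld_info(data.frame(id_a = c("rs2", "rs1"), id_b = c("rs3", "rs4"),
                           r2 = c(0.8, 0.5)))
  pooled2 <- pool_for_mvmr(list(x, m), ld = ld)
  ids <- c("rs1", "rs2", "rs3", "rs4")
  minp <- c(1e-10, 1e-12, 1e-11, 5e-9)
  r2mat <- matrix(0, 4, 4, dimnames = list(ids, ids))
  r2mat["rs2", "rs3"] <- r2mat["rs3", "rs2"] <- 0.8
  r2mat["rs1", "rs4"] <- r2mat["rs4", "rs1"] <- 0.5
  expect_true(clump_oracle_check(ids, minp, r2mat, 0.001, pooled2$variant_id))

  expect_error(pool_for_mvmr(list(x)), class = "mr_usage_error")
})

test_that("instrument strength implements F and both R2 formulas", {
  s <- make_stats(c("rs1", "rs2"), c(0.1, 0), c(0.01, 0.02),
                  pval = c(1e-23, 1), eaf = c(0.5, 0.3))
  st <- instrument_strength(c("rs1", "rs2"), s)
  expect_equal(st$F, c(100, 0))
  expect_equal(st$r2[1], 2 * 0.5 * 0.5 * 0.1^2)
  expect_equal(st$r2[2], 0)
  expect_true(st$weak[2])

  # eaf absent, n present -> F/(F+n-2)
  s2 <- make_stats("rs1", 0.1, 0.01, n = 1000)
  st2 <- instrument_strength("rs1", s2)
  expect_equal(st2$r2, 100 / (100 + 1000 - 2))
  expect_equal(st2$r2_formula, "F/(F+n-2)")

  # both absent -> warning, F only
  s3 <- make_stats("rs1", 0.1, 0.01)
  expect_warning(st3 <- instrument_strength("rs1", s3),
                 class = "mr_strength_unavailable")
  expect_true(is.na(st3$r2))
})

test_that("total R2 recovers the generator's variance explained", {
  cfg <- truth_config(J = 150, theta_direct = 0.2)
  totals <- vapply(1:20, function(i) {
    st <- simulate_study(cfg, seed = 9000 + i)
    inst <- suppressWarnings(select_instruments(st$exposure))
    attr(inst, "total_r2")
  }, numeric(1))
  # truth: sum over exposure instruments of 2 maf (1-maf) gamma^2
  st <- simulate_study(cfg, seed = 9001)
  tr <- st$truth[st$truth$gamma != 0, ]
  truth_r2 <- sum(2 * tr$maf * (1 - tr$maf) * tr$gamma^2)
  expect_lt(abs(mean(totals) - truth_r2) / truth_r2, 0.1)
})

test_that("LD file readers handle long, plink and square formats", {
  dir <- withr::local_tempdir()
  long <- file.path(dir, "ld_long.tsv")
  write.table(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.5), long,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(ld_r2(read_ld(long), "rs2", "rs1"), 0.5)

  plink <- file.path(dir, "ld_plink.tsv")
  write.table(data.frame(CHR_A = 1, BP_A = 100, SNP_A = "rs1", CHR_B = 1,
                         BP_B = 200, SNP_B = "rs2", R2 = 0.25), plink,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(ld_r2(read_ld(plink), "rs1", "rs2"), 0.25)

  sq <- file.path(dir, "ld_sq.tsv")
  m <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(NULL, c("rs1", "rs2")))
  write.table(cbind(data.frame(id = c("rs1", "rs2")), m), sq, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ld <- read_ld(sq)
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.3)
  expect_equal(ld_r2(ld, "rs9", "rs1"), 0)   # missing pair => 0
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)   # self => 1
})
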