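test_that("eQTL selection applies the FDR cut and per-gene cap", {
  tab <- data.frame(
    variant_id = sprintf("rs%d", 1:8),
    gene = c(rep("GENE1", 5), rep("GENE2", 2), "GENE3"),
    effect = rnorm(8),
    fdr = c(1e-6, 1e-5, 1e-5, 1e-3, 0.5, 5e-5, 2e-7, 1e-6))
  sel <- select_eqtls(tab, degs = c("GENE1", "GENE2"))
  expect_identical(sel$variant_id[sel$gene == "GENE1"],
                   c("rs1", "rs2", "rs3"))     # cap 3, worse rows excluded
  expect_identical(sort(sel$variant_id[sel$gene == "GENE2"]),
                   c("rs6", "rs7"))            # under the cap
  expect_false("GENE3" %in% sel$gene)          # not a DEG
  expect_true(all(sel$fdr < 1e-4))
  # deterministic lexicographic tie-break on equal FDR
  tie <- data.frame(variant_id = c("rsB", "rsA", "rsC", "rsD"),
                    gene = "G", effect = 1, fdr = 1e-6)
  expect_identical(select_eqtls(tie, "G")$variant_id,
                   c("rsA", "rsB", "rsC"))
})

test_that("eQTL selection on a simulated 37-gene table obeys the filter oracle", {
  set.seed(101)
  genes <- sprintf("G%02d", 1:37)
  tab <- data.frame(
    variant_id = sprintf("rs%05d", sample(99999, 37 * 6)),
    gene = rep(genes, each = 6),
    effect = rnorm(37 * 6),
    fdr = 10^runif(37 * 6, -8, -2))
  sel <- select_eqtls(tab, genes)
  expect_lte(nrow(sel), 111L)
  expect_true(all(sel$fdr < 1e-4))
  expect_true(all(table(sel$gene) <= 3L))
  # oracle recheck: every selected row is among its gene's 3 best qualifiers
  for (g in unique(sel$gene)) {
    qual <- tab[tab$gene == g & tab$fdr < 1e-4, ]
    best <- head(qual[order(qual$fdr, qual$variant_id), "variant_id"], 3)
    expect_setequal(sel$variant_id[sel$gene == g], best)
  }
})

test_that("phecode table applies the instance, sex and count rules", {
  roster <- data.frame(participant_id = sprintf("S%03d", 1:100),
                       sex = rep(c(1, 0), 50))
  # planted design: S001 two distinct dates (case), S002 two events on the
  # same date (one distinct instance -> missing), S003 one event (missing)
  ev <- data.frame(
    participant_id = c("S001", "S001", "S002", "S002", "S003",
                       rep(sprintf("S%03d", 4:53), each = 2)),
    phecode = "008.0",
    date = c("2020-01-01", "2020-02-01", "2020-03-01", "2020-03-01",
             "2020-04-01",
             paste0("2020-05-", sprintf("%02d", rep(1:2, 50)))))
  pt <- build_phecode_table(ev, roster)
  expect_true(pt$status["S001", "008.0"])
  expect_true(is.na(pt$status["S002", "008.0"]))
  expect_true(is.na(pt$status["S003", "008.0"]))
  expect_false(pt$status["S054", "008.0"])
  expect_identical(unname(pt$n_cases["008.0"]), 51)
  # literal-text variant: single-instance participants become controls
  pt_ctl <- build_phecode_table(ev, roster, one_instance = "control")
  expect_false(pt_ctl$status["S002", "008.0"])
  # sex restriction masks the other sex
  pt_sex <- build_phecode_table(ev, roster,
                                sex_restriction = c("008.0" = "male"))
  females <- roster$participant_id[roster$sex == 0]
  if ("008.0" %in% colnames(pt_sex$status))
    expect_true(all(is.na(pt_sex$status[females, "008.0"])))
  # count filter drops sparse phecodes
  ev_sparse <- ev[1:5, ]; ev_sparse$phecode <- "123.4"
  pt2 <- build_phecode_table(rbind(ev, ev_sparse), roster)
  expect_identical(pt2$dropped, "123.4")
  expect_error(build_phecode_table(
    data.frame(participant_id = "ZZZ", phecode = "1", date = "2020-01-01"),
    roster), "not in roster")
})

test_that("phecode assignments match a direct recount oracle on simulated EHR", {
  gp <- simulate_geno_pheno(600, mafs = c(rs1 = 0.25),
                            betas = matrix(log(1.4), 1, 2,
                                           dimnames = list("rs1",
                                                           c("250.2",
                                                             "401.1"))),
                            beta0 = -1.5, frac_single = 0.08, seed = 103)
  roster <- gp$covariates[, c("participant_id", "sex")]
  pt <- build_phecode_table(gp$events, roster)
  for (ph in colnames(pt$status)) {
    sub <- unique(gp$events[gp$events$phecode == ph,
                            c("participant_id", "date")])
    counts <- table(factor(sub$participant_id,
                           levels = roster$participant_id))
    expected <- as.vector(ifelse(counts >= 2, TRUE,
                                 ifelse(counts == 1, NA, FALSE)))
    expect_identical(unname(pt$status[, ph]), expected)
  }
})

test_that("covariate-free logistic fit reproduces the 2x2 closed-form OR", {
  # cases: 30 exposed / 70 unexposed; controls: 10 exposed / 90 unexposed
  y <- c(rep(TRUE, 100), rep(FALSE, 100))
  dose <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f <- fit_logistic_one(y, dose, data.frame(row.names = seq_along(y)))
  expect_equal(exp(f$beta), 27 / 7, tolerance = 1e-6)
})

test_that("the scan records degenerate fits as missing with reasons", {
  set.seed(104)
  n <- 300
  ids <- sprintf("S%04d", 1:n)
  geno <- cbind(rs_poly = rbinom(n, 2, 0.3), rs_mono = rep(0L, n))
  rownames(geno) <- ids
  covars <- data.frame(participant_id = ids, age = runif(n, 45, 95),
                       sex = rbinom(n, 1, 0.5),
                       matrix(rnorm(n * 6), n, 6,
                              dimnames = list(NULL, paste0("PC", 1:6))),
                       check.names = FALSE)
  status <- matrix(rbinom(n, 1, 0.3) == 1, n, 1,
                   dimnames = list(ids, "008.0"))
  pheno <- list(status = status)
  scan <- logistic_scan(geno, pheno, covars)
  expect_identical(scan$reason[scan$variant == "rs_mono"], "monomorphic")
  expect_true(is.na(scan$OR[scan$variant == "rs_mono"]))
  expect_true(is.na(scan$reason[scan$variant == "rs_poly"]))
  expect_gt(scan$OR[scan$variant == "rs_poly"], 0)
})

test_that("flipping allele coding inverts the OR and keeps the p-value", {
  set.seed(105)
  n <- 800
  ids <- sprintf("S%04d", 1:n)
  dose <- rbinom(n, 2, 0.3)
  covars <- data.frame(participant_id = ids, age = runif(n, 45, 95),
                       sex = rbinom(n, 1, 0.5),
                       matrix(rnorm(n * 6), n, 6,
                              dimnames = list(NULL, paste0("PC", 1:6))),
                       check.names = FALSE)
  eta <- -1 + log(1.6) * dose + 0.02 * (covars$age - 65)
  y <- rbinom(n, 1, plogis(eta)) == 1
  pheno <- function(d) {
    g <- matrix(as.numeric(d), n, 1, dimnames = list(ids, "rs1"))
    logistic_scan(g, list(status = matrix(y, n, 1,
                                          dimnames = list(ids, "250.2"))),
                  covars)
  }
  s1 <- pheno(dose)
  s2 <- pheno(2 - dose)
  expect_equal(s1$OR, 1 / s2$OR, tolerance = 1e-8)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
  # a pure-noise covariate barely moves the estimate
  covars2 <- covars; covars2$PC6 <- rnorm(n)
  g <- matrix(as.numeric(dose), n, 1, dimnames = list(ids, "rs1"))
  st <- list(status = matrix(y, n, 1, dimnames = list(ids, "250.2")))
  s3 <- logistic_scan(g, st, covars2)
  expect_lt(abs(s3$OR - s1$OR) / s1$OR, 0.10)
})

test_that("global and per-variant corrections follow the shared BH oracle", {
  set.seed(106)
  scan <- data.frame(variant = rep(sprintf("rs%d", 1:5), each = 40),
                     phecode = rep(sprintf("%05.1f", 1:40), 5),
                     p = runif(200))
  scan$p[3] <- NA  # one failed fit
  out <- correct_and_report(scan, raw_cut = 1e-4)
  ok <- !is.na(scan$p)
  expect_equal(out$p_adj_global[ok], bh_reference(scan$p[ok]),
               tolerance = 1e-12)
  for (v in unique(scan$variant)) {
    sel <- ok & scan$variant == v
    expect_equal(out$p_adj_eqtl[sel], bh_reference(scan$p[sel]),
                 tolerance = 1e-12)
  }
  expect_true(all(out$p_adj_global[ok] >= scan$p[ok]))
  expect_true(is.na(out$p_adj_global[3]))
  # single-test edge: both adjusted values equal the raw p
  one <- correct_and_report(data.frame(variant = "rs1", phecode = "1",
                                       p = 0.012))
  expect_equal(one$p_adj_global, 0.012)
  expect_equal(one$p_adj_eqtl, 0.012)
  # rank-1 step-up with m tests within a variant
  m <- 1858
  sc <- data.frame(variant = "rs9", phecode = as.character(1:m),
                   p = c(1e-6, rep(1, m - 1)))
  expect_equal(correct_and_report(sc)$p_adj_eqtl[1], 1e-6 * m,
               tolerance = 1e-12)
})

test_that("null-beta scans are calibrated and planted effects are detected", {
  # type-I error at alpha = 0.05 across simulated null phecodes
  gp <- simulate_geno_pheno(1200, mafs = setNames(rep(0.3, 25),
                                                  sprintf("rs%02d", 1:25)),
                            betas = matrix(0, 25, 8,
                                           dimnames = list(
                                             sprintf("rs%02d", 1:25),
                                             sprintf("%05.1f", 1:8))),
                            beta0 = -1.6, seed = 107)
  roster <- gp$covariates[, c("participant_id", "sex")]
  pt <- build_phecode_table(gp$events, roster)
  scan <- logistic_scan(gp$genotypes, pt, gp$covariates)
  p <- scan$p[!is.na(scan$p)]
  expect_gte(length(p), 150)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a planted OR of 1.75 is detected at the reporting threshold", {
  hits <- vapply(1:12, function(s) {
    set.seed(1100 + s)
    n <- 5000
    dose <- rbinom(n, 2, 0.3)
    ids <- sprintf("S%05d", 1:n)
    covars <- data.frame(participant_id = ids, age = runif(n, 45, 95),
                         sex = rbinom(n, 1, 0.5),
                         matrix(rnorm(n * 6), n, 6,
                                dimnames = list(NULL, paste0("PC", 1:6))),
                         check.names = FALSE)
    eta <- qlogis(0.1) + log(1.75) * (dose - mean(dose))
    y <- rbinom(n, 1, plogis(eta)) == 1
    g <- matrix(as.numeric(dose), n, 1, dimnames = list(ids, "rs1"))
    st <- list(status = matrix(y, n, 1, dimnames = list(ids, "530.3")))
    logistic_scan(g, st, covars)$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
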