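#' Select the top eQTLs per differentially expressed gene
#'
#' For each gene in `degs`, keeps the rows of the eQTL summary table with FDR
#' below `fdr_cut`, sorted ascending by FDR (ties broken lexicographically by
#' variant ID), and retains at most `per_gene` of them. A gene with no
#' qualifying eQTL simply contributes none.
#'
#' @param eqtl_table data.frame with columns `variant_id`, `gene`, `effect`,
#'   `fdr`.
#' @param degs character vector of gene IDs.
#' @param per_gene cap per gene; default 3.
#' @param fdr_cut qualifying FDR threshold; default 1e-4.
#' @return the selected subset of `eqtl_table`, one block per gene.
#' @export
select_eqtls <- function(eqtl_table, degs, per_gene = 3L, fdr_cut = 1e-4) {
  stopifnot(all(c("variant_id", "gene", "fdr") %in% names(eqtl_table)))
  keep <- eqtl_table[eqtl_table$gene %in% degs &
                       eqtl_table$fdr < fdr_cut, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  keep <- keep[order(keep$gene, keep$fdr, keep$variant_id), , drop = FALSE]
  idx <- unlist(lapply(split(seq_len(nrow(keep)), keep$gene),
                       utils::head, per_gene), use.names = FALSE)
  out <- keep[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a phecode case/control table from EHR events
#'
#' Applies the phecode phenotyping rules: a participant is a case for a
#' phecode when they have at least two distinct event instances of it
#' (distinct = distinct dates); participants with exactly one instance are
#' excluded (set missing) by default, or counted as controls with
#' `one_instance = "control"`; zero instances means control. Sex-restricted
#' phecodes are then masked to missing for the other sex, and phecodes with
#' fewer than `min_count` cases or fewer than `min_count` controls are
#' dropped.
#'
#' @param events data.frame with columns `participant_id`, `phecode`, `date`.
#' @param roster data.frame with columns `participant_id`, `sex`
#'   (1 = male, 0 = female); every event participant must appear.
#' @param sex_restriction optional named character vector mapping phecode ->
#'   `"male"` or `"female"`.
#' @param min_count minimum cases and minimum controls to retain a phecode;
#'   default 20.
#' @param one_instance `"missing"` (default, exclusion) or `"control"`.
#' @return list with `status` (participants x retained phecodes logical
#'   matrix, `NA` = missing), `n_cases`, `n_controls`, `dropped` (phecodes
#'   removed by the count filter).
#' @export
build_phecode_table <- function(events, roster, sex_restriction = NULL,
                                min_count = 20L,
                                one_instance = c("missing", "control")) {
  one_instance <- match.arg(one_instance)
  stopifnot(all(c("participant_id", "phecode", "date") %in% names(events)),
            all(c("participant_id", "sex") %in% names(roster)))
  unknown <- setdiff(events$participant_id, roster$participant_id)
  if (length(unknown) > 0L)
    stop("event participant(s) not in roster: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  ids <- roster$participant_id
  phecodes <- sort(unique(events$phecode))
  # distinct instances = distinct (participant, phecode, date) triples
  uniq <- unique(events[, c("participant_id", "phecode", "date")])
  counts <- table(factor(uniq$participant_id, levels = ids),
                  factor(uniq$phecode, levels = phecodes))
  status <- matrix(FALSE, length(ids), length(phecodes),
                   dimnames = list(ids, phecodes))
  status[counts >= 2L] <- TRUE
  if (one_instance == "missing") status[counts == 1L] <- NA
  if (!is.null(sex_restriction)) {
    for (ph in intersect(names(sex_restriction), phecodes)) {
      wrong_sex <- if (sex_restriction[[ph]] == "male") roster$sex == 0
                   else roster$sex == 1
      status[wrong_sex, ph] <- NA
    }
  }
  n_cases <- colSums(status, na.rm = TRUE)
  n_controls <- colSums(!status, na.rm = TRUE)
  keep <- n_cases >= min_count & n_controls >= min_count
  list(status = status[, keep, drop = FALSE],
       n_cases = n_cases[keep], n_controls = n_controls[keep],
       dropped = phecodes[!keep])
}

# one covariate-adjusted logistic fit; returns coefficients or a reason code
fit_logistic_one <- function(y, dosage, covar) {
  X <- data.frame(y = y, dosage = dosage, covar)
  fit <- tryCatch(
    stats::glm(y ~ ., data = X, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50L)),
    error = function(e) NULL,
    warning = function(w) suppressWarnings(
      stats::glm(y ~ ., data = X, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 50L))))
  if (is.null(fit)) return(list(reason = "fit_error"))
  if (!fit$converged) return(list(reason = "nonconvergence"))
  beta <- stats::coef(fit)["dosage"]
  if (is.na(beta)) return(list(reason = "inestimable"))
  if (abs(beta) > 15) return(list(reason = "separation"))
  se <- sqrt(diag(stats::vcov(fit))["dosage"])
  list(beta = unname(beta), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(beta / se))), reason = NA_character_)
}

#' Covariate-adjusted logistic PheWAS scan
#'
#' For every (selected variant, retained phecode) pair, fits
#' `logit P(case) = b0 + b * dosage + covariates` by iteratively reweighted
#' least squares (additive allele coding) and records the per-allele odds
#' ratio `exp(b)` with its two-sided Wald p-value. Covariates are age, sex
#' and the first six principal components; sex-restricted phecodes are
#' fitted without the sex covariate (it is constant among the analyzable
#' participants). Monomorphic dosage, single-level outcomes, separation
#' (|b| > 15 on the logit scale) and non-convergence are recorded missing
#' with a reason code rather than dropped silently.
#'
#' @param geno participants x variants dosage matrix (0/1/2), rownames =
#'   participant IDs.
#' @param pheno result of [build_phecode_table()].
#' @param covariates data.frame with `participant_id`, `age`, `sex`,
#'   `PC1`..`PC6`.
#' @param sex_restriction optional named map phecode -> `"male"`/`"female"`.
#' @return data.frame per (variant, phecode): variant, phecode, OR, beta,
#'   se, p, n_cases, n_controls, reason (`NA` when the fit succeeded).
#' @export
logistic_scan <- function(geno, pheno, covariates, sex_restriction = NULL) {
  stopifnot(is.matrix(geno),
            all(c("participant_id", "age", "sex",
                  paste0("PC", 1:6)) %in% names(covariates)))
  ids <- rownames(geno)
  status <- pheno$status
  if (!identical(ids, rownames(status)) ||
      !identical(ids, covariates$participant_id))
    stop("participants not aligned across genotype, phenotype and covariates")
  covar_cols <- c("age", "sex", paste0("PC", 1:6))
  rows <- vector("list", ncol(geno) * ncol(status))
  r <- 0L
  for (v in colnames(geno)) {
    for (ph in colnames(status)) {
      r <- r + 1L
      y <- status[, ph]
      ok <- !is.na(y)
      use_cols <- covar_cols
      if (!is.null(sex_restriction) && ph %in% names(sex_restriction))
        use_cols <- setdiff(use_cols, "sex")
      dose <- geno[ok, v]
      res0 <- list(OR = NA_real_, beta = NA_real_, se = NA_real_,
                   p = NA_real_)
      base <- data.frame(variant = v, phecode = ph,
                         n_cases = sum(y[ok]), n_controls = sum(!y[ok]))
      if (length(unique(dose)) < 2L) {
        rows[[r]] <- cbind(base, res0, reason = "monomorphic")
        next
      }
      if (length(unique(y[ok])) < 2L) {
        rows[[r]] <- cbind(base, res0, reason = "single_outcome_level")
        next
      }
      f <- fit_logistic_one(y[ok], dose, covariates[ok, use_cols,
                                                    drop = FALSE])
      if (!is.na(f$reason)) {
        rows[[r]] <- cbind(base, res0, reason = f$reason)
      } else {
        rows[[r]] <- cbind(base,
                           data.frame(OR = exp(f$beta), beta = f$beta,
                                      se = f$se, p = f$p),
                           reason = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("variant", "phecode", "OR", "beta", "se", "p",
          "n_cases", "n_controls", "reason")]
}

#' Multiple-testing correction and reporting for the PheWAS scan
#'
#' Applies Benjamini-Hochberg twice over the non-missing tests: globally
#' across all association tests (`p_adj_global`) and within each variant's
#' tests (`p_adj_eqtl`). Rows with raw p below `raw_cut` are flagged for
#' reporting, and among those `eqtl_significant` marks per-variant adjusted
#' significance at 0.05.
#'
#' @param scan result of [logistic_scan()].
#' @param raw_cut raw p-value reporting threshold; default 1e-4.
#' @return `scan` with columns `p_adj_global`, `p_adj_eqtl`, `reported`,
#'   `eqtl_significant` added.
#' @export
correct_and_report <- function(scan, raw_cut = 1e-4) {
  stopifnot(all(c("variant", "p") %in% names(scan)))
  ok <- !is.na(scan$p)
  scan$p_adj_global <- NA_real_
  scan$p_adj_global[ok] <- bh_adjust(scan$p[ok])
  scan$p_adj_eqtl <- NA_real_
  for (v in unique(scan$variant)) {
    sel <- ok & scan$variant == v
    if (any(sel)) scan$p_adj_eqtl[sel] <- bh_adjust(scan$p[sel])
  }
  scan$reported <- ok & scan$p < raw_cut
  scan$eqtl_significant <- scan$reported & scan$p_adj_eqtl < 0.05
  scan
}
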