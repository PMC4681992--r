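#' Pathway-level expression from a gene-level view
#'
#' Replaces gene columns by per-pathway means: the expression level of a
#' pathway in a cell line is the average (log2) transcript level of its genes.
#'
#' @param view cell line x gene matrix (named columns).
#' @param pathways named list of gene-name vectors (e.g. from [read_gmt()]).
#' @return Cell line x pathway matrix.
#' @export
pathway_expression <- function(view, pathways) {
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    stopf("'pathways' must be a named list")
  }
  if (any(lengths(pathways) == 0)) stopf("empty pathway")
  missing <- setdiff(unique(unlist(pathways)), colnames(view))
  if (length(missing)) stopf("gene(s) absent from view: %s",
                             paste(utils::head(missing, 10), collapse = ", "))
  m <- vapply(pathways, function(g) rowMeans(view[, g, drop = FALSE]),
              numeric(nrow(view)))
  matrix(m, nrow = nrow(view),
         dimnames = list(rownames(view), names(pathways)))
}

#' Tissue-blocked pathway-drug associations
#'
#' For every (drug, pathway) combination fits the linear model
#' \deqn{pGI_{50} = \beta_p P_i + \beta_T T_i + \varepsilon}
#' across cell lines, where \eqn{P_i} is the pathway's average expression in
#' cell line \eqn{i} and the tissue of origin \eqn{T_i} enters as a blocking
#' factor (reference coding, alphabetically first tissue as baseline; dropped
#' when only one tissue is present). The association strength is
#' \eqn{\beta_p}; its significance is the two-sided t-test p-value, and
#' significance flags control the false discovery rate across pathways within
#' each drug by Benjamini-Hochberg at `fdr_level`.
#'
#' @param drug_profiles drug x cell line matrix of pGI50 values (observed or
#'   model-predicted); `NA` entries are dropped per drug.
#' @param pathway_view cell line x pathway matrix ([pathway_expression()]).
#' @param tissues named character vector, cell line -> tissue.
#' @param fdr_level within-drug FDR level (default 0.20).
#' @return An object of class `association_result`: data frame with one row
#'   per (drug, pathway): `drug, pathway, beta_p, se, p_value, fdr_flag`;
#'   tissue contrasts are kept in the attribute `beta_T` (a named list).
#'   Rank-deficient designs (pathway collinear with the tissue blocks) yield
#'   `NA` coefficients.
#' @export
drug_pathway_associations <- function(drug_profiles, pathway_view, tissues,
                                      fdr_level = 0.2) {
  if (!is.matrix(drug_profiles)) stopf("'drug_profiles' must be a drug x cell line matrix")
  check_fraction(fdr_level, "fdr_level", allow_zero = FALSE, allow_one = TRUE)
  lines <- colnames(drug_profiles)
  if (is.null(lines)) stopf("'drug_profiles' needs cell line column names")
  missing <- setdiff(lines, rownames(pathway_view))
  if (length(missing)) stopf("pathway view lacks cell line(s): %s",
                             paste(missing, collapse = ", "))
  if (!all(lines %in% names(tissues))) stopf("tissue label missing for some cell lines")
  pv <- pathway_view[lines, , drop = FALSE]
  tis <- factor(tissues[lines])
  rows <- list()
  beta_t <- list()
  for (d in rownames(drug_profiles)) {
    y_all <- drug_profiles[d, ]
    ok <- is.finite(y_all)
    y <- y_all[ok]
    t_d <- droplevels(tis[ok])
    blocks <- if (nlevels(t_d) >= 2) stats::model.matrix(~t_d)[, -1, drop = FALSE] else NULL
    for (pw in colnames(pv)) {
      p_i <- pv[ok, pw]
      X <- cbind(`(Intercept)` = 1, P = p_i, blocks)
      beta <- se <- pval <- NA_real_
      if (length(y) >= ncol(X) + 1 && qr(X)$rank == ncol(X)) {
        fit <- stats::lm.fit(X, y)
        rss <- sum(fit$residuals^2)
        df <- length(y) - ncol(X)
        xtxi <- chol2inv(chol(crossprod(X)))
        se_all <- sqrt(diag(xtxi) * rss / df)
        beta <- fit$coefficients["P"]
        se <- se_all[2]
        tval <- beta / se
        pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
        if (!is.null(blocks)) {
          bt <- fit$coefficients[-(1:2)]
          beta_t[[paste(d, pw, sep = "|")]] <- bt
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, pathway = pw, beta_p = unname(beta), se = unname(se),
        p_value = unname(pval), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_flag <- FALSE
  for (d in unique(out$drug)) {
    idx <- which(out$drug == d & !is.na(out$p_value))
    if (length(idx)) {
      out$fdr_flag[idx] <- stats::p.adjust(out$p_value[idx], "BH") < fdr_level
    }
  }
  attr(out, "beta_T") <- beta_t
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("association_result", class(out))
  out
}

#' Consistency of two association tables
#'
#' Per drug, the Spearman rank correlation between the \eqn{\beta_p} vectors
#' of two association results over their shared (drug, pathway) rows —
#' typically associations from experimental profiles versus associations from
#' model-predicted profiles.
#'
#' @param a,b `association_result` objects.
#' @param restrict_to_significant if `TRUE`, use only rows flagged
#'   significant in `a`.
#' @return Data frame `drug, n, r_s` (`r_s` is `NA` with fewer than 3 shared
#'   rows).
#' @export
compare_associations <- function(a, b, restrict_to_significant = FALSE) {
  stopifnot(inherits(a, "association_result"), inherits(b, "association_result"))
  ka <- paste(a$drug, a$pathway, sep = "|")
  kb <- paste(b$drug, b$pathway, sep = "|")
  shared <- intersect(ka, kb)
  a2 <- a[match(shared, ka), ]
  b2 <- b[match(shared, kb), ]
  if (restrict_to_significant) {
    keep <- a2$fdr_flag
    a2 <- a2[keep, ]; b2 <- b2[keep, ]
  }
  out <- lapply(split(seq_len(nrow(a2)), a2$drug), function(idx) {
    ok <- is.finite(a2$beta_p[idx]) & is.finite(b2$beta_p[idx])
    r <- if (sum(ok) >= 3) {
      suppressWarnings(stats::cor(a2$beta_p[idx][ok], b2$beta_p[idx][ok],
                                  method = "spearman"))
    } else NA_real_
    data.frame(drug = a2$drug[idx[1]], n = sum(ok), r_s = r)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Growth-inhibition pattern (z-scores) for one drug
#'
#' Standardizes a drug's per-cell-line pGI50 profile to z-scores (sample sd),
#' the panel's relative sensitivity/resistance pattern. Optional per-line
#' confidence-interval half-widths (e.g. from [predict_interval()]) are
#' carried through on the same scale (divided by the profile sd).
#'
#' @param profile named numeric vector, cell line -> pGI50; needs >= 2 finite,
#'   non-constant values.
#' @param intervals optional named numeric vector of CI half-widths.
#' @return An object of class `inhibition_pattern`: data frame
#'   `cell_line_id, z, ci_half_width`.
#' @export
inhibition_pattern <- function(profile, intervals = NULL) {
  profile <- profile[is.finite(profile)]
  if (length(profile) < 2) stopf("need >= 2 cell lines with values")
  s <- stats::sd(profile)
  if (s == 0) stopf("constant profile; z-scores undefined")
  z <- (profile - mean(profile)) / s
  hw <- rep(NA_real_, length(z))
  if (!is.null(intervals)) {
    hw <- unname(intervals[names(profile)]) / s
  }
  out <- data.frame(cell_line_id = names(profile), z = unname(z),
                    ci_half_width = hw, stringsAsFactors = FALSE)
  class(out) <- c("inhibition_pattern", class(out))
  out
}

#' @export
print.inhibition_pattern <- function(x, ...) {
  cat(sprintf("Growth-inhibition pattern over %d cell lines (z-scores)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}
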