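# Rao's F approximation for Wilks' lambda with p responses, q hypothesis
# df and v error df.
rao_f <- function(lambda, p, q, v) {
  t <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- (v - (p - q + 1) / 2) * t - (p * q) / 2 + 1
  lam_t <- lambda^(1 / t)
  f <- ((1 - lam_t) / lam_t) * df2 / df1
  list(f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-way MANOVA for the age x reserve interaction
#'
#' Fits the five module composites against age group, reserve group and
#' their interaction (type-II sums of squares by default; the
#' interaction term is identical under type III) and tests the
#' interaction with Wilks' lambda and Rao's F approximation. Canonical
#' discriminant functions of the interaction effect are returned with
#' per-group means and structure coefficients; the sign of each function
#' is fixed so that higher cognitive performance loads positive. With
#' `sex` supplied, the model adds sex and the test switches to the
#' three-way age x reserve x sex interaction (the sensitivity analysis).
#'
#' @param composites Numeric matrix, participants x modules (from
#'   [module_composites()]).
#' @param age_group,reserve_group Factors/character vectors per
#'   participant.
#' @param sex Optional factor; triggers the three-way sensitivity model.
#' @param ss_type `"II"` (default) or `"III"`.
#' @return An object of class `connectome_manova`: `wilks_lambda`,
#'   `f_stat`, `df`, `p_value`, `canonical` (list with `coefficients`,
#'   `group_means`, `structure`), `term`, plus the underlying `fit`.
#' @export
connectome_manova <- function(composites, age_group, reserve_group,
                              sex = NULL, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.matrix(composites))
  age_group <- factor(age_group)
  reserve_group <- factor(reserve_group)
  cells <- table(age_group, reserve_group)
  if (any(cells < 2))
    stop("every age x reserve cell needs >= 2 participants")

  df <- data.frame(age_group = age_group,
                   reserve_group = reserve_group)
  if (!is.null(sex)) df$sex <- factor(sex)
  form <- if (is.null(sex))
    composites ~ age_group * reserve_group
  else composites ~ age_group * reserve_group * sex
  environment(form) <- environment()
  if (ss_type == "III") {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
  }
  fit <- stats::lm(form, data = df)
  term <- if (is.null(sex)) "age_group:reserve_group"
          else "age_group:reserve_group:sex"
  p <- ncol(composites)
  if (p >= 2) {
    mv <- tryCatch(
      car::Manova(fit, type = ss_type),
      error = function(e)
        stop("MANOVA failed (likely singular within-group covariance; ",
             "consider reducing responses): ", conditionMessage(e)))
    H <- mv$SSP[[term]]
    E <- mv$SSPE
    q <- mv$df[[term]]
    v <- mv$error.df
  } else {
    # single response: hypothesis/error SS from the univariate table
    a <- car::Anova(fit, type = ss_type)
    it <- which(rownames(a) == term)
    ir <- which(rownames(a) == "Residuals")
    H <- matrix(a$`Sum Sq`[it], dimnames = rep(list(colnames(composites)), 2))
    E <- matrix(a$`Sum Sq`[ir], dimnames = rep(list(colnames(composites)), 2))
    q <- a$Df[it]
    v <- a$Df[ir]
  }
  lambda <- det(E) / det(E + H)
  rf <- rao_f(lambda, p, q, v)

  # Canonical discriminant functions of the tested effect: eigenvectors
  # of E^-1 H (real, nonnegative spectrum since both are PSD).
  eh <- solve(E, H)
  ev <- eigen(eh)
  keep <- seq_len(min(p, q))
  coefs <- Re(ev$vectors[, keep, drop = FALSE])
  # normalize so that t(a) E a / v = 1 (within-group sd 1 on each fn)
  for (k in keep) {
    s <- sqrt(drop(t(coefs[, k]) %*% E %*% coefs[, k]) / v)
    coefs[, k] <- coefs[, k] / s
  }
  centered <- scale(composites, scale = FALSE)
  scores <- centered %*% coefs
  structure_coef <- stats::cor(composites, scores)
  for (k in keep) {
    if (sum(structure_coef[, k]) < 0) {
      coefs[, k] <- -coefs[, k]
      scores[, k] <- -scores[, k]
      structure_coef[, k] <- -structure_coef[, k]
    }
  }
  grp <- interaction(age_group, reserve_group, sep = "_")
  group_means <- apply(scores, 2, function(s) tapply(s, grp, mean))
  colnames(group_means) <- paste0("can", keep)
  rownames(coefs) <- colnames(composites)
  colnames(coefs) <- paste0("can", keep)
  colnames(structure_coef) <- paste0("can", keep)

  structure(
    list(wilks_lambda = lambda, f_stat = rf$f,
         df = c(rf$df1, rf$df2), p_value = rf$p_value,
         eigenvalues = Re(ev$values)[keep],
         canonical = list(coefficients = coefs,
                          group_means = group_means,
                          structure = structure_coef),
         term = term, ss_type = ss_type, fit = fit),
    class = "connectome_manova"
  )
}

#' @export
print.connectome_manova <- function(x, ...) {
  cat("<connectome_manova> interaction term:", x$term, "\n")
  cat(sprintf("  Wilks lambda = %.4f, F(%.0f, %.1f) = %.3f, p = %.4g\n",
              x$wilks_lambda, x$df[1], x$df[2], x$f_stat, x$p_value))
  invisible(x)
}

#' @export
summary.connectome_manova <- function(object, ...) {
  print(object)
  cat("\nGroup means on canonical functions:\n")
  print(round(object$canonical$group_means, 3))
  cat("\nStructure coefficients:\n")
  print(round(object$canonical$structure, 3))
  invisible(object)
}

#' @export
coef.connectome_manova <- function(object, ...) {
  object$canonical$coefficients
}

#' @export
plot.connectome_manova <- function(x, ...) {
  gm <- x$canonical$group_means
  graphics::plot(gm[, 1], seq_len(nrow(gm)), yaxt = "n", pch = 16,
                 xlab = "canonical function 1 (higher = better)",
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(gm)), labels = rownames(gm),
                 las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Follow-up univariate ANOVAs per module
#'
#' Two-way ANOVA (type-II SS) of each module composite on age group,
#' reserve group and their interaction; reports the interaction F and p
#' per module.
#'
#' @inheritParams connectome_manova
#' @return Data frame with `module`, `f`, `df1`, `df2`, `p`.
#' @export
followup_anovas <- function(composites, age_group, reserve_group,
                            ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  age_group <- factor(age_group)
  reserve_group <- factor(reserve_group)
  out <- lapply(colnames(composites), function(m) {
    df <- data.frame(y = composites[, m], age_group = age_group,
                     reserve_group = reserve_group)
    if (ss_type == "III") {
      op <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(op))
    }
    fit <- stats::lm(y ~ age_group * reserve_group, data = df)
    a <- car::Anova(fit, type = ss_type)
    i <- which(rownames(a) == "age_group:reserve_group")
    r <- which(rownames(a) == "Residuals")
    data.frame(module = m, f = a$`F value`[i], df1 = a$Df[i],
               df2 = a$Df[r], p = a$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort descriptives by group
#'
#' Characteristics-of-participants style summary: per six-cell group the
#' n, % women, and mean (SD) of age, MMSE, WAIS-III Information and the
#' five module composites; plus Spearman correlations of MMSE with age
#' and education with WAIS, and a chi-squared test (no continuity
#' correction) of sex against group.
#'
#' @param dataset A preprocessed [cognitive_dataset()] (inverted
#'   z-scores).
#' @param stratification A [stratify()] result.
#' @return List with `table` (data frame, one row per group),
#'   `spearman` (named vector of rho), `sex_chisq` (htest).
#' @export
descriptives <- function(dataset, stratification) {
  comp <- module_composites(dataset)
  d <- dataset$demographics
  grp <- stratification$assignments$group[
    match(d$participant_id, stratification$assignments$participant_id)]
  msd <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  rows <- lapply(group_labels(), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NULL)
    cbind(data.frame(group = g, n = sum(sel),
                     pct_women = round(100 * mean(d$sex[sel] == "F"), 1),
                     age = msd(d$age[sel]), mmse = msd(d$mmse[sel]),
                     wais_info = msd(d$wais_info[sel]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(apply(
            comp[sel, , drop = FALSE], 2, msd)),
            stringsAsFactors = FALSE))
  })
  spearman <- c(
    mmse_age = stats::cor(d$mmse, d$age, method = "spearman"),
    education_wais = stats::cor(as.numeric(d$education_level),
                                d$wais_info, method = "spearman"))
  sex_chisq <- suppressWarnings(
    stats::chisq.test(table(d$sex, grp), correct = FALSE))
  list(table = do.call(rbind, rows), spearman = spearman,
       sex_chisq = sex_chisq)
}
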