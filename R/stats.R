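#' Assemble the subject x condition x ROI analysis table
#'
#' Inner-joins band/ROI entropy with per-subject gaze durations, square-root
#' transforms entropy (the response, to normalize residuals) and z-scores
#' gaze across the subjects present. Subjects missing from either input are
#' dropped with a warning naming them.
#'
#' @param ent data frame from [aggregate_band_roi()] with a `subject`
#'   column; invalid cells (`valid == FALSE` or missing entropy) are
#'   excluded.
#' @param gaze data frame with columns `subject` and `gaze_duration`
#'   (seconds).
#' @return data frame with `subject`, `condition`, `roi`, `sqrt_entropy`,
#'   `gaze_z`; `condition` has reference level `"parallel"` and `roi`
#'   reference level `"other"`.
#' @export
build_analysis_table <- function(ent, gaze) {
  stopifnot(all(c("subject", "condition", "roi", "entropy") %in% names(ent)),
            all(c("subject", "gaze_duration") %in% names(gaze)))
  common <- intersect(unique(ent$subject), unique(gaze$subject))
  dropped <- setdiff(union(unique(ent$subject), unique(gaze$subject)), common)
  if (length(dropped)) {
    warning("subjects missing from one input, dropped: ",
            paste(dropped, collapse = ", "))
  }
  ent <- ent[ent$subject %in% common & is.finite(ent$entropy), , drop = FALSE]
  if ("valid" %in% names(ent)) ent <- ent[ent$valid, , drop = FALSE]
  if (any(ent$entropy < 0)) stop("negative entropy cannot be sqrt-transformed")
  gaze <- gaze[match(common, gaze$subject), ]
  gaze$gaze_z <- zscore(gaze$gaze_duration)
  tab <- merge(ent, gaze[, c("subject", "gaze_z")], by = "subject")
  tab$sqrt_entropy <- sqrt(tab$entropy)
  tab$condition <- stats::relevel(factor(tab$condition), ref = "parallel")
  tab$roi <- stats::relevel(factor(tab$roi), ref = "other")
  tab[order(tab$subject, tab$condition, tab$roi),
      c("subject", "condition", "roi", "sqrt_entropy", "gaze_z")]
}

#' Fit the gaze-entropy general linear model
#'
#' Ordinary least squares of square-root entropy on z-scored parent
#' alternating gaze, with viewing condition and ROI as covariates (main
#' effects, treatment coding; reference levels parallel and "other").
#'
#' @param tab table from [build_analysis_table()].
#' @param cluster_robust also report subject-clustered (CR0) standard
#'   errors alongside the model-based ones. The primary analysis mirrors a
#'   plain GLM that ignores the repeated measures; the robust option is for
#'   users who want a sensitivity check.
#' @return list of class `mseeg_fit`: the `lm` object, a coefficient table,
#'   and the input data.
#' @export
fit_entropy_glm <- function(tab, cluster_robust = FALSE) {
  for (v in c("condition", "roi")) {
    if (nlevels(droplevels(factor(tab[[v]]))) < 2) {
      stop("factor `", v, "` needs at least 2 observed levels")
    }
  }
  fit <- stats::lm(sqrt_entropy ~ gaze_z + condition + roi, data = tab)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient fit; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  ct <- as.data.frame(summary(fit)$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  ct$term <- rownames(ct); rownames(ct) <- NULL
  out <- list(lm = fit, coefficients = ct[, c("term", "estimate", "se", "t", "p")],
              data = tab)
  if (cluster_robust) {
    out$cluster_se <- .cluster_se(fit, tab$subject)
  }
  structure(out, class = "mseeg_fit")
}

# CR0 cluster-robust standard errors by subject
.cluster_se <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  XtXinv <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in split(seq_along(u), cluster)) {
    s <- crossprod(X[g, , drop = FALSE], u[g])
    meat <- meat + tcrossprod(s)
  }
  sqrt(diag(XtXinv %*% meat %*% XtXinv))
}

#' @export
print.mseeg_fit <- function(x, ...) {
  cat("<mseeg_fit>", nrow(x$data), "rows\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Screen residual outliers and influential points
#'
#' Removes rows whose internally studentized residual exceeds
#' `resid_thresh` in absolute value, refits once, then computes Cook's
#' distances on the refit model; rows with D above `cook_thresh` are
#' reported (flagged, not removed). A hard warning is raised when more than
#' 5% of rows are removed, which suggests model misfit rather than stray
#' points.
#'
#' @param fit an `mseeg_fit`.
#' @param resid_thresh standardized-residual cut-off.
#' @param cook_thresh Cook's distance cut-off.
#' @return an `mseeg_fit` for the refit model, with `removed` (row indices
#'   of the original table), `cooks` (distances on the refit) and
#'   `influential` (flagged rows of the refit data).
#' @export
screen_outliers <- function(fit, resid_thresh = 3, cook_thresh = 1) {
  stopifnot(inherits(fit, "mseeg_fit"))
  rs <- stats::rstandard(fit$lm)
  remove <- unname(which(abs(rs) > resid_thresh))
  if (length(remove) > 0.05 * nrow(fit$data)) {
    warning(sprintf(
      "%d of %d rows exceed |standardized residual| > %g; model misfit likely",
      length(remove), nrow(fit$data), resid_thresh))
  }
  kept <- fit$data
  if (length(remove)) kept <- kept[-remove, , drop = FALSE]
  refit <- fit_entropy_glm(kept)
  cooks <- stats::cooks.distance(refit$lm)
  refit$removed <- remove
  refit$cooks <- cooks
  refit$influential <- which(cooks > cook_thresh)
  refit$n_removed <- length(remove)
  refit
}

#' ROI estimated marginal means and pairwise contrasts
#'
#' EMMs per ROI at `gaze_z = 0`, averaged over viewing condition, with all
#' pairwise ROI contrasts under Tukey adjustment.
#'
#' @param fit an `mseeg_fit` whose model contains `roi`.
#' @return list with `emm` (ROI, emmean, SE, CI) and `contrasts` (pairs,
#'   estimate, SE, t, Tukey-adjusted p) data frames.
#' @export
emm_roi_contrasts <- function(fit) {
  stopifnot(inherits(fit, "mseeg_fit"))
  em <- emmeans::emmeans(fit$lm, ~roi, at = list(gaze_z = 0))
  ctr <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  list(emm = as.data.frame(em), contrasts = as.data.frame(ctr))
}

#' Simulate an analysis table with known coefficients
#'
#' Generates a subject x condition x ROI table directly at the statistics
#' stage (bypassing EEG synthesis) under the fitted model's own error
#' assumptions — independent homoscedastic Gaussian residuals — so that
#' type-I error and power of the gaze coefficient can be calibrated against
#' nominal levels. Each subject receives one standard-normal gaze score;
#' the response is built from the linear predictor plus noise.
#'
#' @param n_subjects number of subjects.
#' @param beta_gaze true gaze slope on the sqrt-entropy scale.
#' @param beta_condition true joint-vs-parallel offset.
#' @param roi_effects named numeric offsets for ROIs (reference `"other"`).
#' @param intercept mean response at the reference levels.
#' @param resid_sd residual standard deviation.
#' @return a table suitable for [fit_entropy_glm()], with attribute
#'   `truth` recording the generating coefficients.
#' @export
simulate_stats_table <- function(n_subjects = 61, beta_gaze = 0.013,
                                 beta_condition = 0.007,
                                 roi_effects = c(LF = 0, RF = 0, LC = 0, RC = 0),
                                 intercept = 0.85, resid_sd = 0.16) {
  rois <- c("other", "LF", "RF", "LC", "RC")
  conds <- c("parallel", "joint")
  gaze <- stats::rnorm(n_subjects)
  tab <- expand.grid(subject = sprintf("S%03d", seq_len(n_subjects)),
                     condition = conds, roi = rois,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$gaze_z <- gaze[match(tab$subject, sprintf("S%03d", seq_len(n_subjects)))]
  eta <- intercept + beta_gaze * tab$gaze_z +
    beta_condition * (tab$condition == "joint") +
    ifelse(tab$roi == "other", 0, roi_effects[tab$roi])
  tab$sqrt_entropy <- eta + stats::rnorm(nrow(tab), sd = resid_sd)
  tab$condition <- stats::relevel(factor(tab$condition), ref = "parallel")
  tab$roi <- stats::relevel(factor(tab$roi), ref = "other")
  attr(tab, "truth") <- list(beta_gaze = beta_gaze,
                             beta_condition = beta_condition,
                             roi_effects = roi_effects,
                             intercept = intercept, resid_sd = resid_sd)
  tab
}
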