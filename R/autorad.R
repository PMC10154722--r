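#' Fit a robust standard curve to film calibration points
#'
#' Calibrates film optical density (OD) against tritium standards of known
#' activity with an iteratively reweighted least-squares (IRLS) fit using a
#' redescending Tukey bisquare weight, so that a grossly aberrant standard is
#' effectively removed from the fit. The primary model is the monotone
#' saturating film response
#' \deqn{OD = b + A (1 - e^{-k \cdot activity}), \quad A, k > 0,}
#' which captures the approach of the emulsion to its maximum density. When
#' saturation is not identifiable from the points (the data are linear over
#' the calibrated range, or the nonlinear fit does not converge) the fit
#' falls back to a robust straight line `OD = b + m * activity` with the same
#' IRLS machinery.
#'
#' @param activity known standard activities (micro-Ci/mg tissue
#'   equivalent), length >= 4 with >= 3 distinct values.
#' @param od measured optical densities.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   weight vector.
#' @return Object of class `calibration_curve`: list with `family`
#'   (`"saturating"` or `"linear"`), `coef`, `weights` (per standard point),
#'   `od_range` (ODs invertible by [interpolate_activity()]), and the input
#'   points.
#' @export
fit_standard_curve <- function(activity, od, max_iter = 100, tol = 1e-8) {
  stopifnot(is.numeric(activity), is.numeric(od),
            length(activity) == length(od), all(is.finite(activity)),
            all(is.finite(od)))
  if (length(activity) < 4) stop("need >= 4 standard points")
  if (length(unique(activity)) < 3) stop("need >= 3 distinct activities")
  if (any(activity < 0)) stop("negative standard activity")

  ## monotonicity screen: per-activity mean ODs must increase overall
  act_u <- sort(unique(activity))
  mu <- as.numeric(tapply(od, factor(activity, levels = act_u), mean))
  ktau <- stats::cor(act_u, mu, method = "kendall")
  if (is.na(ktau) || ktau <= 0)
    stop("standards are not monotone increasing in activity")

  lin <- irls_linear(activity, od, max_iter, tol)
  ## exact straight line: saturation unidentifiable by construction
  if (max(abs(lin$resid)) <= 1e-8 * max(diff(range(od)), 1)) {
    return(curve_from_linear(lin, activity, od))
  }
  sat <- tryCatch(irls_saturating(activity, od, max_iter, tol),
                  error = function(e) NULL)
  if (is.null(sat) || sat$coef[["k"]] * max(activity) < 0.05) {
    ## curvature negligible over the calibrated range -> linear fallback
    return(curve_from_linear(lin, activity, od))
  }
  if (sat$coef[["A"]] <= 0 || sat$coef[["k"]] <= 0)
    stop("fitted curve is not monotone increasing")
  structure(list(family = "saturating", coef = sat$coef,
                 weights = sat$w,
                 od_range = c(sat$coef[["b"]],
                              sat$coef[["b"]] + sat$coef[["A"]]),
                 activity = activity, od = od),
            class = "calibration_curve")
}

curve_from_linear <- function(lin, activity, od) {
  if (lin$coef[["m"]] <= 0) stop("fitted curve is not monotone increasing")
  structure(list(family = "linear", coef = lin$coef, weights = lin$w,
                 od_range = c(lin$coef[["b"]], Inf),
                 activity = activity, od = od),
            class = "calibration_curve")
}

## bisquare weights with a MAD scale; guard against zero scale on exact fits
bisquare_w <- function(r, cc = 4.685) {
  s <- stats::median(abs(r)) / 0.6745
  s <- max(s, 1e-10, 1e-8 * max(abs(r)))
  u <- r / (cc * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  ## keep the system well-posed if too many points are zero-weighted
  if (sum(w > 0) < 3) w <- pmax(w, 1e-6)
  w
}

irls_linear <- function(x, y, max_iter, tol) {
  w <- rep(1, length(x))
  for (i in seq_len(max_iter)) {
    fit <- stats::lm.wfit(cbind(b = 1, m = x), y, w)
    r <- y - cbind(1, x) %*% fit$coefficients
    w_new <- bisquare_w(as.numeric(r))
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  cf <- fit$coefficients
  names(cf) <- c("b", "m")
  list(coef = cf, w = w, resid = as.numeric(r))
}

irls_saturating <- function(x, y, max_iter, tol) {
  b0 <- min(y)
  a0 <- max(max(y) - min(y), 1e-3) * 1.5
  k0 <- 1 / max(stats::median(x[x > 0]), 1e-6)
  w <- rep(1, length(x))
  dat <- data.frame(x = x, y = y)
  start <- list(b = b0, A = a0, k = k0)
  for (i in seq_len(max_iter)) {
    dat$w_ <- w
    fit <- minpack.lm::nlsLM(y ~ b + A * (1 - exp(-k * x)), data = dat,
                             start = start, weights = w_,
                             lower = c(b = -Inf, A = 1e-10, k = 1e-10),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    r <- y - (cf[["b"]] + cf[["A"]] * (1 - exp(-cf[["k"]] * x)))
    start <- as.list(cf)
    w_new <- bisquare_w(r)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  list(coef = cf, w = w, resid = r)
}

#' Evaluate a calibration curve (activity -> OD)
#'
#' @param curve a `calibration_curve`.
#' @param activity activities to convert.
#' @return Predicted optical densities.
#' @export
predict_od <- function(curve, activity) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- curve$coef
  if (curve$family == "saturating")
    cf[["b"]] + cf[["A"]] * (1 - exp(-cf[["k"]] * activity))
  else
    cf[["b"]] + cf[["m"]] * activity
}

#' Invert a calibration curve (OD -> activity)
#'
#' Unique inverse read-out of the monotone standard curve. ODs at or above
#' the saturation asymptote of a saturating curve cannot be inverted and
#' raise an error naming the limit. ODs below the curve baseline are handled
#' by `below`: `"clamp"` (default) maps them to activity 0 with a warning,
#' `"error"` rejects them, `"allow"` returns the algebraic inverse (possibly
#' negative; linear family only).
#'
#' @param curve a `calibration_curve`.
#' @param od optical densities to invert.
#' @param below policy for ODs below the baseline.
#' @return Activities (micro-Ci/mg), same length as `od`.
#' @export
interpolate_activity <- function(curve, od,
                                 below = c("clamp", "error", "allow")) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(od))
  below <- match.arg(below)
  cf <- curve$coef
  b <- cf[["b"]]
  low <- od < b
  if (any(low)) {
    if (below == "error")
      stop("OD below calibration baseline ", signif(b, 6))
    if (below == "clamp")
      warning(sum(low), " OD value(s) below baseline clamped to activity 0")
  }
  if (curve$family == "saturating") {
    sat <- b + cf[["A"]]
    if (any(od >= sat))
      stop("OD at/above saturation asymptote ", signif(sat, 6),
           "; not invertible")
    act <- -log(1 - (od - b) / cf[["A"]]) / cf[["k"]]
  } else {
    act <- (od - b) / cf[["m"]]
  }
  if (below == "clamp") act[low] <- 0
  act
}

#' Specific binding from total and nonspecific activity
#'
#' `specific = total - nonspecific`; when no nonspecific condition exists for
#' a ligand (displaceable binding absent), the total is taken as specific.
#' Negative differences are retained but flagged (attribute
#' `flag_negative`), with a warning.
#'
#' @param total total-binding activity (micro-Ci/mg).
#' @param nonspecific nonspecific-binding activity, or `NULL` when absent.
#' @return Numeric vector of specific binding with logical attribute
#'   `flag_negative`.
#' @export
compute_specific_binding <- function(total, nonspecific = NULL) {
  stopifnot(is.numeric(total), all(is.finite(total)))
  if (is.null(nonspecific)) {
    out <- total
  } else {
    stopifnot(is.numeric(nonspecific),
              length(nonspecific) %in% c(1L, length(total)))
    out <- total - nonspecific
  }
  neg <- out < 0
  if (any(neg)) warning(sum(neg), " negative specific-binding value(s) flagged")
  attr(out, "flag_negative") <- neg
  out
}

#' Average converted section activities into a per-subject binding table
#'
#' Takes a long section table whose ODs have already been converted to
#' activity, averages the (typically 3) consecutive sections per subject and
#' ROI within each condition, and subtracts the nonspecific mean from the
#' total mean ([compute_specific_binding()]). Subject x ROI combinations
#' without any total-condition section are recorded as missing (`NA`), never
#' imputed.
#'
#' @param sections data frame with columns `subject`, `genotype`, `roi`,
#'   `section`, `condition` (`"total"` or `"nonspecific"`), `activity`.
#' @return Binding table: `subject`, `genotype`, `roi`, `value`
#'   (micro-Ci/mg specific binding), `flag_negative`.
#' @export
aggregate_sections <- function(sections) {
  stopifnot(is.data.frame(sections))
  need <- c("subject", "genotype", "roi", "section", "condition", "activity")
  miss <- setdiff(need, names(sections))
  if (length(miss))
    stop("section table lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(sections$condition %in% c("total", "nonspecific")))

  subj_geno <- unique(sections[, c("subject", "genotype")])
  rois <- unique(as.character(sections$roi))
  grid <- expand.grid(subject = subj_geno$subject, roi = rois,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, subj_geno, by = "subject", sort = FALSE)

  key <- function(d) paste(d$subject, d$roi)
  tot <- sections[sections$condition == "total", , drop = FALSE]
  nsp <- sections[sections$condition == "nonspecific", , drop = FALSE]
  tot_mean <- tapply(tot$activity, key(tot), mean)
  nsp_mean <- if (nrow(nsp)) tapply(nsp$activity, key(nsp), mean) else NULL

  gk <- key(grid)
  total <- as.numeric(tot_mean[gk])
  value <- rep(NA_real_, nrow(grid))
  flag <- rep(FALSE, nrow(grid))
  has <- !is.na(total)
  if (any(has)) {
    ns <- if (is.null(nsp_mean)) NULL else as.numeric(nsp_mean[gk[has]])
    if (!is.null(ns) && all(is.na(ns))) ns <- NULL
    if (!is.null(ns)) ns[is.na(ns)] <- 0  # no nonspecific section measured
    sp <- withCallingHandlers(
      compute_specific_binding(total[has], ns),
      warning = function(w) invokeRestart("muffleWarning"))
    value[has] <- as.numeric(sp)
    flag[has] <- attr(sp, "flag_negative")
  }
  out <- data.frame(subject = grid$subject, genotype = grid$genotype,
                    roi = grid$roi, value = value, flag_negative = flag,
                    stringsAsFactors = FALSE)
  out[order(out$subject, out$roi), , drop = FALSE]
}

#' Full film quantification chain
#'
#' Fits one robust standard curve per film ([fit_standard_curve()]),
#' converts every section OD on that film to activity
#' ([interpolate_activity()]), then averages sections and subtracts
#' nonspecific binding ([aggregate_sections()]). Conversion happens per
#' section, before averaging, because the film response is nonlinear.
#'
#' @param standards data frame `film`, `activity`, `od`.
#' @param sections data frame `film`, `subject`, `genotype`, `roi`,
#'   `section`, `condition`, `od`.
#' @param below below-baseline OD policy, see [interpolate_activity()].
#' @return List with `binding` (per-subject binding table) and `curves`
#'   (named list of per-film `calibration_curve` objects).
#' @export
quantify_binding <- function(standards, sections, below = "clamp") {
  stopifnot(all(c("film", "activity", "od") %in% names(standards)),
            all(c("film", "subject", "genotype", "roi", "section",
                  "condition", "od") %in% names(sections)))
  films <- unique(as.character(standards$film))
  unknown <- setdiff(unique(as.character(sections$film)), films)
  if (length(unknown))
    stop("sections reference film(s) without standards: ",
         paste(unknown, collapse = ", "))
  curves <- lapply(films, function(f) {
    s <- standards[standards$film == f, , drop = FALSE]
    fit_standard_curve(s$activity, s$od)
  })
  names(curves) <- films
  sections$activity <- NA_real_
  for (f in films) {
    i <- sections$film == f
    if (any(i))
      sections$activity[i] <-
        interpolate_activity(curves[[f]], sections$od[i], below = below)
  }
  list(binding = aggregate_sections(sections), curves = curves)
}
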