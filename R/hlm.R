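#' Join acoustic features with the participant manifest
#'
#' Inner join on \code{participant_id} with integrity checks on the dyadic
#' design: every id unique, every pair exactly two members sharing gender
#' and country. Rows with missing AQ are retained and flagged; listwise
#' deletion happens only at fit time (and is logged there).
#'
#' @param features Data frame with at least \code{participant_id},
#'   \code{area_px}, \code{articulation_time_s}.
#' @param manifest Data frame with \code{participant_id}, \code{pair_id},
#'   \code{gender}, \code{country}, \code{age}, \code{cr}, \code{aq}.
#' @return A participant-record data frame (one row per speaker) with a
#'   logical \code{aq_missing} column.
#' @export
assemble_dataset <- function(features, manifest) {
  if (anyDuplicated(manifest$participant_id)) {
    stop("duplicate participant_id in manifest: ",
         paste(unique(manifest$participant_id[duplicated(manifest$participant_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(features$participant_id)) {
    stop("duplicate participant_id in features", call. = FALSE)
  }
  missing_feat <- setdiff(manifest$participant_id, features$participant_id)
  if (length(missing_feat)) {
    stop("manifest rows without feature rows: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  rec <- merge(manifest,
               features[, intersect(c("participant_id", "area_px",
                                      "articulation_time_s"),
                                    names(features))],
               by = "participant_id", sort = TRUE)
  if (!"duration" %in% names(rec) && "articulation_time_s" %in% names(rec)) {
    rec$duration <- rec$articulation_time_s
  }

  sizes <- table(rec$pair_id)
  if (any(sizes != 2)) {
    stop("pairs without exactly 2 members: ",
         paste(names(sizes)[sizes != 2], collapse = ", "), call. = FALSE)
  }
  by_pair <- split(rec, rec$pair_id)
  bad <- vapply(by_pair, function(p) {
    length(unique(p$gender)) != 1 || length(unique(p$country)) != 1
  }, logical(1))
  if (any(bad)) {
    stop("pairs with mixed gender or country: ",
         paste(names(by_pair)[bad], collapse = ", "), call. = FALSE)
  }
  rec$aq_missing <- is.na(rec$aq)
  rec
}

# Design coding shared by the cohort generator and the model fit.
# "simple" coding: gender male-female coded -0.5/+0.5 (effect reads
# "2-1" = male - female); country simple-coded against Italy (columns read
# India-Italy and UK-Italy) so the intercept sits at the unweighted grand
# mean; covariates grand-mean-centered. "treatment": conventional dummy
# coding with uncentered covariates.
hlm_design <- function(records, coding = c("simple", "treatment"),
                       centers = NULL) {
  coding <- match.arg(coding)
  gender <- factor(records$gender, levels = c("female", "male"))
  country <- factor(records$country, levels = c("Italy", "India", "UK"))
  if (anyNA(gender)) stop("gender must be 'female' or 'male'", call. = FALSE)
  if (anyNA(country)) stop("country must be Italy, India or UK", call. = FALSE)

  covs <- c("age", "duration", "cr", "aq")
  if (coding == "simple") {
    if (is.null(centers)) {
      centers <- vapply(covs, function(v) mean(records[[v]], na.rm = TRUE),
                        numeric(1))
    }
    X <- data.frame(
      gender = ifelse(gender == "male", 0.5, -0.5),
      country_india = (country == "India") - 1 / 3,
      country_uk = (country == "UK") - 1 / 3,
      age = records$age - centers[["age"]],
      duration = records$duration - centers[["duration"]],
      cr = records$cr - centers[["cr"]],
      aq = records$aq - centers[["aq"]]
    )
  } else {
    centers <- c(age = 0, duration = 0, cr = 0, aq = 0)
    X <- data.frame(
      gender = as.numeric(gender == "male"),
      country_india = as.numeric(country == "India"),
      country_uk = as.numeric(country == "UK"),
      age = records$age, duration = records$duration,
      cr = records$cr, aq = records$aq
    )
  }
  labels <- if (coding == "simple") {
    c("(Intercept)", "2-1", "India-Italy", "UK-Italy",
      "Age", "Duration", "CR", "AQ")
  } else {
    c("(Intercept)", "male-female", "India", "UK",
      "Age", "Duration", "CR", "AQ")
  }
  list(X = X, labels = labels, coding = coding, centers = centers)
}

#' Fit the hierarchical linear model of articulation space
#'
#' REML fit of \code{area_px ~ gender + country + age + duration + cr + aq}
#' with a random intercept per pair, via \code{lmerTest}. Inference uses
#' Satterthwaite approximate degrees of freedom (hence fractional df) and
#' two-sided t tests; confidence intervals are
#' \code{estimate +/- t(df, 1 - alpha/2) * SE}.
#'
#' With the default \code{"simple"} coding the gender effect reads
#' male - female ("2-1"), the country effects India - Italy and UK - Italy,
#' the covariates are grand-mean-centered, and the intercept sits near the
#' grand mean of articulation space.
#'
#' @param records Participant-record data frame (see
#'   \code{\link{assemble_dataset}}): \code{participant_id},
#'   \code{pair_id}, \code{gender}, \code{country}, \code{age},
#'   \code{duration}, \code{cr}, \code{aq}, \code{area_px}.
#' @param coding \code{"simple"} (default) or \code{"treatment"}.
#' @param ci_level Confidence level. Default 0.95.
#' @return An object of class \code{hlm_result}: \code{fixed_effects}
#'   (term, label, estimate, se, ci_lo, ci_hi, df, t, p), \code{var_pair},
#'   \code{var_resid}, \code{n_obs}, \code{n_pairs}, \code{n_dropped},
#'   \code{fit_meta}, and the underlying \code{fit}.
#' @export
fit_hlm <- function(records, coding = c("simple", "treatment"),
                    ci_level = 0.95) {
  coding <- match.arg(coding)
  used <- c("pair_id", "gender", "country", "age", "duration", "cr", "aq",
            "area_px")
  miss <- setdiff(used, names(records))
  if (length(miss)) stop("records lack columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(records[, used])
  n_dropped <- sum(!complete)
  rec <- records[complete, , drop = FALSE]
  if (length(unique(rec$pair_id)) < 3) {
    stop("need at least 3 pairs to fit the model", call. = FALSE)
  }

  des <- hlm_design(rec, coding)
  X <- cbind(`(Intercept)` = 1, as.matrix(des$X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  dat <- cbind(des$X, area_px = rec$area_px,
               pair_id = factor(rec$pair_id))
  fit <- tryCatch(
    lmerTest::lmer(area_px ~ gender + country_india + country_uk + age +
                     duration + cr + aq + (1 | pair_id),
                   data = dat, REML = TRUE),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e), call. = FALSE))
  sm <- summary(fit, ddf = "Satterthwaite")
  co <- sm$coefficients
  alpha <- 1 - ci_level
  tq <- stats::qt(1 - alpha / 2, co[, "df"])

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_pair <- vc$vcov[vc$grp == "pair_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]

  structure(list(
    fixed_effects = data.frame(
      term = rownames(co),
      label = des$labels,
      estimate = co[, "Estimate"],
      se = co[, "Std. Error"],
      ci_lo = co[, "Estimate"] - tq * co[, "Std. Error"],
      ci_hi = co[, "Estimate"] + tq * co[, "Std. Error"],
      df = co[, "df"],
      t = co[, "t value"],
      p = co[, "Pr(>|t|)"],
      row.names = NULL
    ),
    var_pair = var_pair,
    var_resid = var_resid,
    n_obs = nrow(rec),
    n_pairs = length(unique(rec$pair_id)),
    n_dropped = n_dropped,
    fit_meta = list(method = "REML", coding = coding,
                    ddf = "Satterthwaite", ci_level = ci_level,
                    centers = des$centers),
    fit = fit
  ), class = "hlm_result")
}

#' @export
print.hlm_result <- function(x, ...) {
  cat(sprintf(
    "Hierarchical linear model of articulation space (REML, %s coding)\n",
    x$fit_meta$coding))
  cat(sprintf("n = %d participants in %d pairs (%d dropped for missingness)\n",
              x$n_obs, x$n_pairs, x$n_dropped))
  fe <- x$fixed_effects
  fe_num <- fe[, c("estimate", "se", "ci_lo", "ci_hi", "df", "t", "p")]
  fe_fmt <- cbind(fe[, c("term", "label")],
                  round(fe_num, 3))
  print(fe_fmt, row.names = FALSE)
  cat(sprintf("Random intercept (pair) variance: %.2f; residual: %.2f\n",
              x$var_pair, x$var_resid))
  invisible(x)
}

#' Descriptive statistics by country and gender
#'
#' N, mean and SD of closeness rating, AQ and articulation space for each
#' country split by gender, with per-country totals. Missing AQ values are
#' excluded cell-wise, with N reflecting availability; the SD of a single
#' observation is reported as NA.
#'
#' @param records Participant-record data frame.
#' @return A long data frame: \code{country}, \code{group}
#'   (male/female/total), \code{measure} (cr/aq/area_px), \code{n},
#'   \code{mean}, \code{sd}.
#' @export
descriptives <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  measures <- c("cr", "aq", "area_px")
  cell <- function(x) {
    x <- x[!is.na(x)]
    data.frame(n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  out <- list()
  for (ctry in unique(records$country)) {
    rc <- records[records$country == ctry, ]
    groups <- list(male = rc[rc$gender == "male", ],
                   female = rc[rc$gender == "female", ],
                   total = rc)
    for (g in names(groups)) {
      for (m in measures) {
        s <- cell(groups[[g]][[m]])
        out[[length(out) + 1]] <- cbind(
          data.frame(country = ctry, group = g, measure = m), s)
      }
    }
  }
  do.call(rbind, out)
}
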