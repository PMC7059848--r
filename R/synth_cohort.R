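#' Study-sized dyadic design
#'
#' Pair counts per country and gender mirroring the three-country study:
#' India 9 male + 13 female pairs, Italy 10 + 10, UK 18 + 25 -- 85 pairs,
#' 170 speakers in all.
#'
#' @return Data frame with columns \code{country}, \code{gender},
#'   \code{n_pairs}.
#' @export
study_design <- function() {
  data.frame(
    country = rep(c("India", "Italy", "UK"), each = 2),
    gender = rep(c("male", "female"), 3),
    n_pairs = c(9, 13, 10, 10, 18, 25)
  )
}

#' Default generating coefficients for synthetic cohorts
#'
#' On the package's simple coding (gender male - female; country effects
#' against Italy; covariates grand-mean-centered). Defaults are
#' study-plausible effect sizes: a grand-mean intercept around 256 px, a
#' ~51 px male-female difference, a negative India offset, a ~5.6 px/point
#' closeness slope and a ~-1.8 px/point AQ slope.
#'
#' @return Named numeric vector.
#' @export
default_betas <- function() {
  c(intercept = 255.655, gender = 51.015,
    country_india = -47.394, country_uk = 13.184,
    age = 2.507, duration = -0.168, cr = 5.603, aq = -1.834)
}

#' Generate a dyadic cohort with known fixed and random effects
#'
#' The generative twin of the articulation-space mixed model:
#' \deqn{area = X\beta + u_{pair} + e,\quad u \sim N(0, sd\_pair^2),\quad
#'       e \sim N(0, sd\_resid^2)}
#' with \eqn{X} built on the same simple coding the fit uses (so recovery
#' tests compare like with like). Both members of a pair share the pair
#' intercept, country and gender. Covariates are drawn independently by
#' default: closeness rating integer 0-10, AQ integer 5-40, age integer
#' 18-33, duration uniform 120-180 s (the ~2.5 minute speaking task). An
#' optional \code{cr_aq_cor} draws CR and AQ from a Gaussian copula for
#' robustness checks.
#'
#' @param design Data frame of \code{country}, \code{gender},
#'   \code{n_pairs} cells. Default \code{\link{study_design}()}.
#' @param betas Named coefficients (see \code{\link{default_betas}}).
#' @param sd_pair Random-intercept SD. Default 30.
#' @param sd_resid Residual SD. Default 50.
#' @param missing_aq_pairs Number of pairs whose AQ is set missing.
#'   Default 0.
#' @param cr_aq_cor Latent correlation between CR and AQ. Default 0.
#' @param seed Integer seed; fixes the cohort exactly.
#' @return A list: \code{records} (participant-record data frame) and
#'   \code{truth} (betas, SDs, coding, covariate centers used).
#' @export
generate_cohort <- function(design = study_design(),
                            betas = default_betas(),
                            sd_pair = 30, sd_resid = 50,
                            missing_aq_pairs = 0,
                            cr_aq_cor = 0,
                            seed = 1) {
  needed <- c("intercept", "gender", "country_india", "country_uk",
              "age", "duration", "cr", "aq")
  if (!all(needed %in% names(betas))) {
    stop("betas must be named: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (sd_pair < 0 || sd_resid < 0) stop("SDs must be >= 0", call. = FALSE)

  with_seed(seed, {
    pairs <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      if (d$n_pairs == 0) return(NULL)
      data.frame(country = d$country, gender = d$gender,
                 cell_pair = seq_len(d$n_pairs))
    }))
    n_pairs <- nrow(pairs)
    pairs$pair_id <- sprintf("P%03d", seq_len(n_pairs))
    pairs$u <- stats::rnorm(n_pairs, 0, sd_pair)

    rec <- pairs[rep(seq_len(n_pairs), each = 2), ]
    n <- nrow(rec)
    rec$participant_id <- sprintf("%s_%d", rec$pair_id, rep(1:2, n_pairs))
    rec$age <- sample(18:33, n, replace = TRUE)
    rec$duration <- stats::runif(n, 120, 180)
    if (cr_aq_cor != 0) {
      z1 <- stats::rnorm(n)
      z2 <- cr_aq_cor * z1 + sqrt(1 - cr_aq_cor^2) * stats::rnorm(n)
      rec$cr <- pmin(10, pmax(0, round(5 + 2.5 * z1)))
      rec$aq <- pmin(40, pmax(5, round(20 + 7 * z2)))
    } else {
      rec$cr <- sample(0:10, n, replace = TRUE)
      rec$aq <- sample(5:40, n, replace = TRUE)
    }

    des <- hlm_design(rec, "simple")
    b <- betas[c("gender", "country_india", "country_uk",
                 "age", "duration", "cr", "aq")]
    eta <- betas[["intercept"]] + as.matrix(des$X) %*% b
    rec$area_px <- as.numeric(eta) + rec$u + stats::rnorm(n, 0, sd_resid)

    if (missing_aq_pairs > 0) {
      drop <- sample(unique(rec$pair_id), missing_aq_pairs)
      rec$aq[rec$pair_id %in% drop] <- NA
    }

    rownames(rec) <- NULL
    rec$u <- NULL; rec$cell_pair <- NULL
    rec <- rec[, c("participant_id", "pair_id", "gender", "country",
                   "age", "duration", "cr", "aq", "area_px")]
    list(records = rec,
         truth = list(betas = betas, sd_pair = sd_pair, sd_resid = sd_resid,
                      coding = "simple", centers = des$centers,
                      n_pairs = n_pairs, seed = seed))
  })
}
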