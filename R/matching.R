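sample_ids_of <- function(metadata) {
  if (!is.null(metadata$sample_id)) as.character(metadata$sample_id)
  else rownames(metadata)
}

#' Fit a propensity model for diagnosis
#'
#' Maximum-likelihood logistic regression of case status on clinical
#' covariates (default sex and age). Covariates are standardised internally
#' for numerical stability and coefficients reported on the original scale.
#' Quasi-separation is flagged (and warned) when fitted probabilities reach
#' 0/1 numerically.
#'
#' @param metadata per-sample data.frame with a `diagnosis` column and the
#'   covariates; one row per sample (deduplicate subjects first if needed).
#' @param covariates metadata columns to use (default `c("sex", "age")`).
#' @return object of class `PropensityModel`: coefficients, per-sample
#'   `score` (probability) and `logit`, the `separation` flag and sample ids.
#' @export
fitPropensity <- function(metadata, covariates = c("sex", "age")) {
  y <- as_binary01(metadata$diagnosis)
  if (length(unique(y)) < 2) stop("both diagnosis classes required")
  X <- metadata[, covariates, drop = FALSE]
  Xn <- as.data.frame(lapply(X, function(v) {
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) > 2) stop("only binary categorical covariates supported")
      as.numeric(as.character(v) == lev[length(lev)])
    } else as.numeric(v)
  }))
  ctr <- vapply(Xn, mean, 1); scl <- vapply(Xn, stats::sd, 1)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(Xn, 2, ctr), 2, scl, "/")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, Z), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && (!fit$converged ||
               any(fit$fitted.values > 1 - 1e-8 |
                   fit$fitted.values < 1e-8)))
    sep <- TRUE
  if (sep) warning("quasi-separation detected in the propensity fit")
  bz <- stats::coef(fit)
  bz[is.na(bz)] <- 0          # aliased (constant) covariates drop out
  beta <- bz[-1] / scl
  intercept <- bz[1] - sum(bz[-1] * ctr / scl)
  logit <- as.numeric(intercept + as.matrix(Xn) %*% beta)
  structure(list(coefficients = c("(Intercept)" = unname(intercept),
                                  stats::setNames(beta, covariates)),
                 score = stats::plogis(logit), logit = logit,
                 separation = sep, sample_id = sample_ids_of(metadata),
                 diagnosis = y),
            class = "PropensityModel")
}

#' @export
print.PropensityModel <- function(x, ...) {
  cat("PropensityModel on", length(x$logit), "samples\n")
  print(round(x$coefficients, 4))
  if (x$separation) cat(" (quasi-separation flagged)\n")
  invisible(x)
}

#' Greedy nearest-neighbour propensity matching
#'
#' 1:1 matching without replacement on the propensity logit. The minority
#' class drives the matching; its members are processed in descending logit
#' order, each taking the nearest still-available majority sample. Ties are
#' broken by lexical sample-id order, so the output is deterministic. Pairs
#' whose logit distance exceeds the caliper (if given) are discarded.
#'
#' @param model a `PropensityModel` from [fitPropensity()].
#' @param metadata the metadata the model was fitted on.
#' @param caliper optional maximal logit distance.
#' @return object of class `MatchedCohort`: `pairs` (case_id, control_id,
#'   distance) and `matched_ids`.
#' @export
matchNearest <- function(model, metadata, caliper = NULL) {
  ids <- model$sample_id
  y <- model$diagnosis
  lg <- model$logit
  if (!any(y == 1) || !any(y == 0)) stop("both diagnosis classes required")
  minority <- if (sum(y == 1) <= sum(y == 0)) 1 else 0
  di <- which(y == minority)
  dj <- which(y != minority)
  ## descending logit order, sample id as total tie-break
  di <- di[order(-lg[di], ids[di])]
  avail <- rep(TRUE, length(dj))
  pairs <- list()
  for (i in di) {
    cand <- dj[avail]
    if (!length(cand)) break
    d <- abs(lg[cand] - lg[i])
    best <- cand[order(d, ids[cand])][1]
    dist <- abs(lg[best] - lg[i])
    if (!is.null(caliper) && dist > caliper) next
    avail[match(best, dj)] <- FALSE
    caseId <- if (minority == 1) ids[i] else ids[best]
    ctlId <- if (minority == 1) ids[best] else ids[i]
    pairs[[length(pairs) + 1L]] <-
      data.frame(case_id = caseId, control_id = ctlId, distance = dist,
                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(case_id = character(), control_id = character(),
                           distance = numeric())
  structure(list(pairs = pairs,
                 matched_ids = c(pairs$case_id, pairs$control_id)),
            class = "MatchedCohort")
}

#' @export
print.MatchedCohort <- function(x, ...) {
  cat("MatchedCohort:", nrow(x$pairs), "pairs (",
      length(x$matched_ids), "samples )\n")
  invisible(x)
}

smd_one <- function(v, y) {
  if (is.character(v) || is.factor(v)) {
    lev <- sort(unique(as.character(v)))
    v <- as.numeric(as.character(v) == lev[length(lev)])
    p1 <- mean(v[y == 1]); p0 <- mean(v[y == 0])
    s2 <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    num <- p1 - p0
  } else {
    s2 <- (stats::var(v[y == 1]) + stats::var(v[y == 0])) / 2
    num <- mean(v[y == 1]) - mean(v[y == 0])
  }
  if (!is.finite(s2) || s2 == 0)
    return(c(smd = 0, degenerate = 1))
  c(smd = num / sqrt(s2), degenerate = 0)
}

#' Covariate balance diagnostics
#'
#' Standardised mean difference (SMD) per covariate before and after
#' matching: `(mean_case - mean_control) / sqrt((s1^2 + s0^2)/2)`, with
#' proportions for binary covariates. Zero pooled variance is reported as
#' SMD 0 with a flag.
#'
#' @param cohort a `MatchedCohort` from [matchNearest()].
#' @param metadata the full metadata the matching drew from.
#' @param covariates metadata columns to assess.
#' @return data.frame with columns covariate, smd_before, smd_after,
#'   degenerate.
#' @export
balanceDiagnostics <- function(cohort, metadata,
                               covariates = c("sex", "age")) {
  if (!nrow(cohort$pairs)) stop("matched cohort is empty")
  ids <- sample_ids_of(metadata)
  y <- as_binary01(metadata$diagnosis)
  sel <- ids %in% cohort$matched_ids
  out <- lapply(covariates, function(cv) {
    b <- smd_one(metadata[[cv]], y)
    a <- smd_one(metadata[[cv]][sel], y[sel])
    data.frame(covariate = cv, smd_before = unname(b["smd"]),
               smd_after = unname(a["smd"]),
               degenerate = b["degenerate"] == 1 | a["degenerate"] == 1)
  })
  do.call(rbind, out)
}
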