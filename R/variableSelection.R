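# Two-step variable selection: (1) iterative collinearity exclusion keeping
# all surviving pairwise |r| below a threshold, resolving each offending pair
# by variance inflation factor; (2) retention of variables contributing at
# least a threshold share to a presence-background model, with contributions
# from a jackknife (leave-one-variable-out) gain decomposition.

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` is the coefficient of
#' determination of variable k regressed on all the others. A perfectly
#' collinear variable gets `Inf`, never an exception. A single-column matrix
#' returns `VIF = 1`.
#'
#' @param values numeric matrix, points x variables (>= 3 rows, no constant
#'   column).
#' @return named numeric vector of VIFs (each >= 1).
#' @export
vif <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 3L)
  nm <- colnames(values) %||% paste0("v", seq_len(ncol(values)))
  colnames(values) <- nm
  if (any(apply(values, 2L, stats::sd) == 0)) stop("constant column in VIF input")
  if (ncol(values) == 1L) return(setNames(1, nm))
  out <- setNames(numeric(ncol(values)), nm)
  for (k in seq_len(ncol(values))) {
    fit <- stats::lm.fit(cbind(1, values[, -k, drop = FALSE]), values[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((values[, k] - mean(values[, k]))^2)
    r2 <- 1 - rss / tss
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  pmax(out, 1)
}

#' Iterative collinearity filter
#'
#' While any surviving pair of variables has `|Pearson r|` at or above the
#' threshold, the pair with maximal `|r|` is found and the member with the
#' larger VIF (computed on the current survivor set) is dropped; ties drop
#' the lexicographically later name. On exit every surviving pairwise
#' `|r|` is below the threshold.
#'
#' @param values numeric matrix, points x variables (>= 2 variables).
#' @param threshold pairwise correlation threshold, default 0.7.
#' @return list with `kept` (ordered names), `dropped` (data.frame name /
#'   partner / abs_r / vif), and `cor` (the full initial correlation matrix).
#' @export
collinearityFilter <- function(values, threshold = 0.7) {
  values <- as.matrix(values)
  stopifnot(ncol(values) >= 2L, threshold > 0, threshold < 1)
  nm <- colnames(values) %||% paste0("v", seq_len(ncol(values)))
  colnames(values) <- nm
  fullCor <- stats::cor(values)
  alive <- nm
  dropped <- data.frame(name = character(), partner = character(),
                        abs_r = numeric(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    if (length(alive) < 2L) break
    cm <- abs(stats::cor(values[, alive, drop = FALSE]))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx < threshold) break
    ix <- which(cm == mx, arr.ind = TRUE)[1L, ]
    pair <- sort(c(alive[ix[1L]], alive[ix[2L]]))
    vifs <- vif(values[, alive, drop = FALSE])[pair]
    # drop the larger-VIF member; ties go against the later name
    loser <- if (vifs[1L] > vifs[2L]) pair[1L]
             else if (vifs[2L] > vifs[1L]) pair[2L]
             else pair[2L]
    keeper <- setdiff(pair, loser)
    dropped <- rbind(dropped, data.frame(name = loser, partner = keeper,
                                         abs_r = mx, vif = unname(vifs[loser]),
                                         stringsAsFactors = FALSE))
    alive <- setdiff(alive, loser)
  }
  if (length(alive) == 0L) stop("no variables survive collinearity filter")
  list(kept = nm[nm %in% alive], dropped = dropped, cor = fullCor)
}

# log-likelihood-based gain of a ridge presence-background classifier,
# relative to the intercept-only model, per observation.
pbGain <- function(x, y, lambda = 0.01) {
  if (ncol(x) == 0L) return(0)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  p <- as.numeric(stats::predict(fit, newx = x, type = "response"))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  p0 <- mean(y)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  (ll - ll0) / length(y)
}

# linear + quadratic feature expansion
pbFeatures <- function(values) {
  values <- as.matrix(values)
  cbind(values, values^2)
}

#' Jackknife-gain variable importance for a presence-background model
#'
#' Default importance estimator: an L2-regularised logistic
#' presence-background classifier with linear + quadratic features is fitted
#' with all variables, then without each variable in turn. A variable's raw
#' contribution is the drop in model gain (per-observation log-likelihood
#' improvement over the null) when it is excluded; when no exclusion changes
#' the gain, the single-variable gains are used instead. Contributions are
#' scaled to sum to 100.
#'
#' @param presence,background numeric matrices sharing columns.
#' @param lambda ridge penalty of the classifier.
#' @return named numeric vector of percentage contributions (sums to 100).
#' @export
jackknifeGain <- function(presence, background, lambda = 0.01) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  stopifnot(identical(colnames(presence), colnames(background)),
            ncol(presence) >= 1L)
  nm <- colnames(presence) %||% paste0("v", seq_len(ncol(presence)))
  k <- length(nm)
  if (k == 1L) return(setNames(100, nm))
  x <- rbind(presence, background)
  colnames(x) <- nm
  y <- c(rep(1, nrow(presence)), rep(0, nrow(background)))
  featIx <- function(keep) c(keep, keep + k)   # linear + quadratic columns
  xf <- pbFeatures(x)
  gFull <- pbGain(xf, y, lambda)
  drops <- setNames(numeric(k), nm)
  for (j in seq_len(k))
    drops[j] <- max(0, gFull - pbGain(xf[, featIx(setdiff(seq_len(k), j)), drop = FALSE],
                                      y, lambda))
  if (sum(drops) <= 0) {
    for (j in seq_len(k))
      drops[j] <- max(0, pbGain(xf[, featIx(j), drop = FALSE], y, lambda))
  }
  if (sum(drops) <= 0) drops[] <- 1   # completely uninformative: uniform split
  100 * drops / sum(drops)
}

#' Importance filter: keep variables contributing at least a threshold share
#'
#' Runs the configured presence-background importance estimator and keeps
#' variables whose percentage contribution reaches
#' `contributionThreshold`. When every variable falls below the threshold the
#' single best one is kept with a warning, so selection never empties.
#'
#' @param presence,background numeric matrices sharing columns (standardised
#'   values at presence and background locations).
#' @param contributionThreshold percent, default 5.
#' @param estimator a function `(presence, background) -> named percentage
#'   vector summing to 100`; default [jackknifeGain()]. An external
#'   presence-background implementation (e.g. a Maxent wrapper) can be
#'   plugged in here.
#' @return list with `kept`, `dropped` (data.frame name / contribution), and
#'   `contributions` (all candidates).
#' @export
importanceFilter <- function(presence, background, contributionThreshold = 5,
                             estimator = jackknifeGain) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  stopifnot(ncol(presence) == ncol(background),
            contributionThreshold >= 0, contributionThreshold < 100)
  if (nrow(presence) < 10L)
    warning("fewer than 10 presence records; importance estimates will be unstable")
  contrib <- estimator(presence, background)
  if (abs(sum(contrib) - 100) > 1e-6 || any(contrib < 0))
    stop("importance estimator must return non-negative contributions summing to 100")
  keep <- contrib >= contributionThreshold
  if (!any(keep)) {
    warning("no variable reaches the contribution threshold; keeping the best one")
    keep[which.max(contrib)] <- TRUE
  }
  list(kept = names(contrib)[keep],
       dropped = data.frame(name = names(contrib)[!keep],
                            contribution = unname(contrib[!keep]),
                            stringsAsFactors = FALSE),
       contributions = contrib)
}

#' Full two-step variable selection
#'
#' Collinearity exclusion followed by the importance filter, with a combined
#' report suitable for serialisation.
#'
#' @param presence,background numeric matrices sharing columns.
#' @param correlationThreshold pairwise `|r|` threshold, default 0.7.
#' @param contributionThreshold percent contribution threshold, default 5.
#' @param estimator importance estimator, see [importanceFilter()].
#' @return list with `kept`, `droppedCollinear`, `droppedLowContribution`,
#'   `contributions`, `vif`, and `cor`.
#' @export
selectVariables <- function(presence, background, correlationThreshold = 0.7,
                            contributionThreshold = 5, estimator = jackknifeGain) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  stopifnot(identical(colnames(presence), colnames(background)))
  both <- rbind(presence, background)
  if (ncol(both) >= 2L) {
    step1 <- collinearityFilter(both, threshold = correlationThreshold)
  } else {
    step1 <- list(kept = colnames(both), dropped = data.frame(), cor = stats::cor(both))
  }
  step2 <- importanceFilter(presence[, step1$kept, drop = FALSE],
                            background[, step1$kept, drop = FALSE],
                            contributionThreshold = contributionThreshold,
                            estimator = estimator)
  list(kept = step2$kept,
       droppedCollinear = step1$dropped,
       droppedLowContribution = step2$dropped,
       contributions = step2$contributions,
       vif = vif(both[, step1$kept, drop = FALSE]),
       cor = step1$cor)
}

#' Write a variable-selection report as JSON
#'
#' @param selection result of [selectVariables()].
#' @param path output file.
#' @export
writeSelectionReport <- function(selection, path) {
  jsonlite::write_json(list(
    kept = selection$kept,
    dropped_collinear = selection$droppedCollinear,
    dropped_low_contribution = selection$droppedLowContribution,
    contributions = as.list(selection$contributions),
    vif = as.list(selection$vif),
    cor = selection$cor
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
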