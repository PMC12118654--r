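## Nested Monte-Carlo ranking of contextual parameters, majority-vote
## prognostic classifier, and survival evaluation. The resampling loops use a
## hand-written chi-square log-rank (src/core.cpp) for speed; survival::
## survdiff / coxph / survfit provide the user-facing standard statistics
## and serve as independent cross-checks in the test suite.

.lr_p <- function(time, event, group) {
  ## group: integer 0/1. Returns p = 1 for degenerate comparisons.
  if (length(unique(group)) < 2L) return(1)
  st <- cpp_logrank(as.numeric(time), as.integer(event), as.integer(group))
  if (st[2] <= 0) return(1)
  stats::pchisq(st[1], df = 1, lower.tail = FALSE)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank with hypergeometric variance; symmetric in
#' the group order. A comparison with no information (no events at shared
#' risk times) returns statistic 0 and p = 1, flagged degenerate.
#'
#' @param times_a,events_a,times_b,events_b survival times (years) and event
#'   indicators of the two groups.
#' @return list: `chi2`, `p`, `degenerate`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) >= 1, length(times_b) >= 1)
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- c(rep(0L, length(times_a)), rep(1L, length(times_b)))
  st <- cpp_logrank(as.numeric(time), as.integer(event), group)
  if (st[2] <= 0) return(list(chi2 = 0, p = 1, degenerate = TRUE))
  list(chi2 = st[1], p = stats::pchisq(st[1], df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Median split of parameter values
#'
#' Patients are stably sorted by (value, id) and divided into a lower and an
#' upper half (equal halves for even n; the lower half is the smaller for
#' odd n). A parameter whose values are all tied cannot be split.
#'
#' @param values numeric vector (no missing values).
#' @param ids tie-breaking identifiers (defaults to position).
#' @return list: `low` and `high` index vectors into `values`.
#' @export
median_split <- function(values, ids = seq_along(values)) {
  if (length(values) < 2) stop("need >= 2 patients to split")
  if (anyNA(values)) stop("values must be defined")
  if (length(unique(values)) == 1L)
    stop("all values tied; median split is unstable")
  ord <- order(values, ids)
  nlow <- length(values) %/% 2L
  list(low = ord[seq_len(nlow)], high = ord[(nlow + 1L):length(values)])
}

.param_matrix <- function(parameters) {
  if (is.data.frame(parameters)) {
    num <- vapply(parameters, is.numeric, TRUE)
    num["patient_id" == names(parameters)] <- FALSE
    X <- as.matrix(parameters[, num, drop = FALSE])
  } else X <- as.matrix(parameters)
  storage.mode(X) <- "double"
  X
}

#' Inner Monte-Carlo resampling loop
#'
#' Each repetition draws `n_select` patients without replacement, median-
#' splits them per parameter, and log-rank-tests the two halves. Upon
#' significance (p < alpha) the half with the smaller Kaplan-Meier area
#' (restricted mean survival) is the "shorter-survival" group, and the two
#' group means of the parameter are recorded. After all repetitions the
#' recorded observations are averaged; parameters never significant are
#' excluded. Repetitions where a parameter is missing or fully tied are
#' skipped for that parameter.
#'
#' @param parameters patient x parameter data frame or matrix.
#' @param time,event survival times (years) and event flags, parallel to the
#'   parameter rows.
#' @param n_select patients drawn per repetition.
#' @param reps repetitions.
#' @param alpha log-rank significance level.
#' @param seed RNG seed (optional; the caller may manage the RNG instead).
#' @return data frame: `parameter`, `n_significant_reps`, `mean_short`,
#'   `mean_long`, ordered as the input columns; attribute `skipped`.
#' @export
inner_loop <- function(parameters, time, event, n_select = 12, reps = 1000,
                       alpha = 0.05, seed = NULL) {
  X <- .param_matrix(parameters)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (nrow(X) < n_select) stop("cohort smaller than n_select")
  run <- function() cpp_inner_loop(X, as.numeric(time), as.integer(event),
                                   as.integer(n_select), as.integer(reps),
                                   alpha)
  res <- if (is.null(seed)) run() else .with_seed(seed, run())
  keep <- res$n_significant >= 1L
  out <- data.frame(parameter = colnames(X)[keep],
                    n_significant_reps = res$n_significant[keep],
                    mean_short = res$sum_short[keep] / res$n_significant[keep],
                    mean_long = res$sum_long[keep] / res$n_significant[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- stats::setNames(res$skipped, colnames(X))
  out
}

#' Majority-vote prognosis classification
#'
#' Each model parameter votes "long" when the patient's value is at least as
#' close to the recorded longer-survival mean as to the shorter-survival
#' mean (equidistant values vote long), and "short" otherwise; missing
#' values abstain. A majority of long votes gives "good" prognosis; a tie or
#' a short majority gives "bad" (conservative tie rule); a patient with no
#' defined model parameter is unclassifiable (`NA`).
#'
#' @param parameters patient x parameter data frame or matrix.
#' @param model a `classifier_model` from [build_final_classifier()].
#' @return character vector "good"/"bad" (NA = unclassifiable).
#' @export
classify_patients <- function(parameters, model) {
  stopifnot(inherits(model, "classifier_model"))
  X <- .param_matrix(parameters)
  missing <- setdiff(model$parameter, colnames(X))
  if (length(missing))
    stop("parameter table lacks model parameter(s): ",
         paste(missing, collapse = ", "))
  V <- X[, model$parameter, drop = FALSE]
  d_long <- abs(sweep(V, 2L, model$mean_long))
  d_short <- abs(sweep(V, 2L, model$mean_short))
  long_vote <- d_long <= d_short           # equidistant -> long
  n_long <- rowSums(long_vote, na.rm = TRUE)
  n_def <- rowSums(!is.na(long_vote))
  out <- ifelse(n_long > n_def - n_long, "good", "bad")
  out[n_def == 0L] <- NA_character_
  out
}

## Balanced train/test split: shorter- and longer-than-median survivors are
## divided as evenly as parity allows, re-drawn until the two sets do not
## differ in survival (log-rank p > alpha) or the retry cap is hit.
.balanced_split <- function(time, event, train_n, alpha = 0.05, tries = 100) {
  n <- length(time)
  med <- stats::median(time)
  shorter <- which(time < med)
  longer <- setdiff(seq_len(n), shorter)
  best <- NULL
  for (k in seq_len(tries)) {
    ns_train <- if (length(shorter) %% 2L == 0L) length(shorter) %/% 2L
    else length(shorter) %/% 2L + sample(0:1, 1)
    ns_train <- min(max(ns_train, train_n - length(longer)), train_n)
    tr <- c(sample(shorter, ns_train),
            sample(longer, train_n - ns_train))
    te <- setdiff(seq_len(n), tr)
    p <- .lr_p(time, event, as.integer(seq_len(n) %in% tr))
    if (is.null(best) || p > best$p) best <- list(train = tr, test = te, p = p)
    if (p > alpha) break
  }
  best
}

#' Rank contextual parameters by prognostic value (outer Monte-Carlo loop)
#'
#' Each outer repetition (1) splits the cohort into balanced train and test
#' sets, (2) runs [inner_loop()] on the train set, (3) ranks the surviving
#' parameters by the log-rank p of their individual closer-to-mean split of
#' the train set — those significant at `alpha` are the interim classifier
#' candidates, (4) prunes the worst-p candidate from the interim
#' majority-vote classifier until the classifier splits the train set
#' significantly, and (5) applies the surviving interim classifier to the
#' test set: if the test split is also significant, every retained parameter
#' scores one hit. Hit counts over all repetitions rank the parameters.
#'
#' @param parameters patient x parameter data frame (the 50-column center
#'   shortlist in the reference workflow).
#' @param time,event survival data parallel to the rows.
#' @param outer_reps,inner_reps Monte-Carlo repetitions of the two loops.
#' @param n_select inner-loop draw size.
#' @param alpha significance level used throughout.
#' @param seed RNG seed.
#' @return object of class `ranking_result`: `hits` (named integer vector)
#'   and `log` (one row per outer repetition).
#' @export
rank_parameters <- function(parameters, time, event, outer_reps = 1000,
                            inner_reps = 1000, n_select = 12, alpha = 0.05,
                            seed = NULL) {
  X <- .param_matrix(parameters)
  run <- function() {
    hits <- stats::setNames(integer(ncol(X)), colnames(X))
    log_rows <- vector("list", outer_reps)
    train_n <- nrow(X) %/% 2L
    for (rep_i in seq_len(outer_reps)) {
      sp <- .balanced_split(time, event, train_n, alpha)
      tr <- sp$train; te <- sp$test
      pm <- inner_loop(X[tr, , drop = FALSE], time[tr], event[tr],
                       n_select = n_select, reps = inner_reps, alpha = alpha)
      entry <- list(rep = rep_i, split_p = sp$p, n_candidates = nrow(pm),
                    n_final = 0L, p_train = NA_real_, p_test = NA_real_,
                    hit = FALSE, parameters = "")
      if (nrow(pm) >= 1L) {
        ## rank candidates by their individual closer-to-mean train split
        p_ind <- vapply(seq_len(nrow(pm)), function(j) {
          v <- X[tr, pm$parameter[j]]
          grp <- as.integer(abs(v - pm$mean_long[j]) <= abs(v - pm$mean_short[j]))
          grp[is.na(v)] <- NA_integer_
          ok <- !is.na(grp)
          if (sum(ok) < 2) return(1)
          .lr_p(time[tr][ok], event[tr][ok], grp[ok])
        }, 0)
        ## candidates: parameters whose individual split separates the train
        ## set significantly, best first (the interim classifier is built
        ## from the parameters that perform, then pruned from the worst end)
        cand <- which(p_ind < alpha)
        active <- cand[order(p_ind[cand])]
        p_train <- NA_real_
        while (length(active) >= 1L) {
          grp <- classify_patients(X[tr, , drop = FALSE],
                                   structure(pm[active, , drop = FALSE],
                                             class = c("classifier_model",
                                                       "data.frame")))
          p_train <- .lr_p(time[tr][!is.na(grp)], event[tr][!is.na(grp)],
                           as.integer(grp[!is.na(grp)] == "good"))
          if (p_train < alpha) break
          active <- active[-length(active)]   # drop worst-ranked parameter
        }
        if (length(active) >= 1L && !is.na(p_train) && p_train < alpha) {
          final <- structure(pm[active, , drop = FALSE],
                             class = c("classifier_model", "data.frame"))
          grp_te <- classify_patients(X[te, , drop = FALSE], final)
          ok <- !is.na(grp_te)
          p_test <- .lr_p(time[te][ok], event[te][ok],
                          as.integer(grp_te[ok] == "good"))
          entry$n_final <- length(active)
          entry$p_train <- p_train
          entry$p_test <- p_test
          entry$parameters <- paste(pm$parameter[active], collapse = ";")
          if (p_test < alpha) {
            hits[pm$parameter[active]] <- hits[pm$parameter[active]] + 1L
            entry$hit <- TRUE
          }
        }
      }
      log_rows[[rep_i]] <- as.data.frame(entry, stringsAsFactors = FALSE)
    }
    structure(list(hits = hits, log = do.call(rbind, log_rows)),
              class = "ranking_result")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' @export
print.ranking_result <- function(x, n = 10, ...) {
  cat(sprintf("ranking_result: %d outer repetitions, %d hits total\n",
              nrow(x$log), sum(x$log$hit)))
  top <- sort(x$hits, decreasing = TRUE)[seq_len(min(n, length(x$hits)))]
  for (i in seq_along(top))
    cat(sprintf("  %2d. %-45s %d hits\n", i, names(top)[i], top[i]))
  invisible(x)
}

#' Build the final majority-vote classifier
#'
#' Runs the inner resampling loop over the full cohort restricted to the top
#' parameters; parameters significant in at least one repetition are
#' retained with their recorded shorter/longer-survival means.
#'
#' @param parameters patient x parameter data frame.
#' @param time,event survival data.
#' @param top_params parameter names to consider (e.g. the top-10 by hits).
#' @param reps,alpha,n_select inner-loop controls.
#' @param seed RNG seed.
#' @return object of class `classifier_model` (data frame: parameter,
#'   n_significant_reps, mean_short, mean_long), ordered by
#'   n_significant_reps.
#' @export
build_final_classifier <- function(parameters, time, event, top_params,
                                   reps = 1000, alpha = 0.05, n_select = 12,
                                   seed = NULL) {
  X <- .param_matrix(parameters)
  missing <- setdiff(top_params, colnames(X))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  pm <- inner_loop(X[, top_params, drop = FALSE], time, event,
                   n_select = n_select, reps = reps, alpha = alpha,
                   seed = seed)
  if (nrow(pm) == 0L) stop("no classifier: no parameter reached significance")
  pm <- pm[order(-pm$n_significant_reps, pm$parameter), , drop = FALSE]
  rownames(pm) <- NULL
  attr(pm, "skipped") <- NULL
  structure(pm, class = c("classifier_model", "data.frame"))
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %d parameter(s), majority vote\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-45s short %.4g | long %.4g (%d sig. reps)\n",
                x$parameter[i], x$mean_short[i], x$mean_long[i],
                x$n_significant_reps[i]))
  invisible(x)
}

#' Save / load a classifier model as JSON
#' @param model a `classifier_model`.
#' @param path JSON file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  jsonlite::write_json(as.data.frame(model), path, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(df), class = c("classifier_model", "data.frame"))
}

#' Evaluate a classifier's survival separation
#'
#' Classifies the cohort, fits Kaplan-Meier curves per predicted group,
#' reads overall survival at 5 and 10 years, and tests the separation with a
#' log-rank test.
#'
#' @param model a `classifier_model`.
#' @param parameters,time,event cohort data.
#' @return list: `status` ("ok" or "degenerate"), `groups` (table), `os`
#'   (data frame: group, os5, os10), `logrank_p`, `fit` (survfit object).
#' @export
evaluate_classifier <- function(model, parameters, time, event) {
  grp <- classify_patients(parameters, model)
  ok <- !is.na(grp)
  if (length(unique(grp[ok])) < 2L) {
    return(list(status = "degenerate", groups = table(grp[ok]),
                os = NULL, logrank_p = NA_real_, fit = NULL))
  }
  g <- factor(grp[ok], levels = c("good", "bad"))
  fit <- survival::survfit(survival::Surv(time[ok], event[ok]) ~ g)
  sm <- summary(fit, times = c(5, 10), extend = TRUE)
  strata <- sub("^g=", "", as.character(sm$strata))
  os <- data.frame(group = c("good", "bad"),
                   os5 = sm$surv[sm$time == 5][match(c("good", "bad"),
                                                     strata[sm$time == 5])],
                   os10 = sm$surv[sm$time == 10][match(c("good", "bad"),
                                                       strata[sm$time == 10])],
                   stringsAsFactors = FALSE)
  lr <- logrank_test(time[ok][g == "good"], event[ok][g == "good"],
                     time[ok][g == "bad"], event[ok][g == "bad"])
  list(status = "ok", groups = table(g), os = os, logrank_p = lr$p, fit = fit)
}

#' Cox proportional-hazards regression with Breslow ties
#'
#' Univariate or multivariate partial-likelihood fit (Breslow tie handling)
#' for binary group indicators (e.g. median-split indicators), returning
#' hazard ratios with Wald 95% confidence intervals.
#'
#' @param covariates vector, matrix or data frame of covariates.
#' @param time,event survival data.
#' @return data frame: term, hr, ci_low, ci_high, p; attribute `converged`.
#' @export
cox_regression <- function(covariates, time, event) {
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1) stop("need at least one event")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "converged") <- fit$info["convergence"] == 0 ||
    is.null(fit$info)
  out
}

#' Sensitivity and specificity for extreme survivors
#'
#' Restricts the cohort to short survivors (event before `short_cut` years)
#' and long survivors (observed beyond `long_cut` years) and scores the
#' classifier: sensitivity = fraction of short survivors classified "bad",
#' specificity = fraction of long survivors classified "good".
#'
#' @param model a `classifier_model`.
#' @param parameters,time,event cohort data.
#' @param short_cut,long_cut stratum cut points in years.
#' @return list: sensitivity, specificity, n_short, n_long.
#' @export
sensitivity_specificity <- function(model, parameters, time, event,
                                    short_cut = 5, long_cut = 10) {
  grp <- classify_patients(parameters, model)
  short_i <- which(event == 1 & time < short_cut & !is.na(grp))
  long_i <- which(time > long_cut & !is.na(grp))
  sens <- if (length(short_i)) mean(grp[short_i] == "bad") else NA_real_
  spec <- if (length(long_i)) mean(grp[long_i] == "good") else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_short = length(short_i), n_long = length(long_i))
}

#' Pairwise rank correlations of a parameter table
#'
#' Spearman correlations with two-sided p-values; missing values are
#' pairwise-deleted. Constant columns yield `NA`.
#'
#' @param parameters patient x parameter data frame or matrix.
#' @param method correlation method (rank-based by default).
#' @return list: `rho` and `p` matrices.
#' @export
correlate_parameters <- function(parameters, method = "spearman") {
  X <- .param_matrix(parameters)
  if (nrow(X) < 3) stop("need >= 3 patients")
  p <- ncol(X)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  pv <- rho
  for (i in seq_len(p)) for (j in i:p) {
    ok <- stats::complete.cases(X[, i], X[, j])
    if (sum(ok) >= 3 && stats::sd(X[ok, i]) > 0 && stats::sd(X[ok, j]) > 0) {
      ct <- suppressWarnings(stats::cor.test(X[ok, i], X[ok, j],
                                             method = method, exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = pv)
}
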