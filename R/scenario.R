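#' Scenario configuration
#'
#' Loads and validates a simulation-scenario configuration from YAML or JSON.
#' Required fields: `mechanism`, `n`, `miss`. Defaults: `m = 10`,
#' `cycles = 5`, `donors = 5`, `reps = 1`, `B = 100`, `threshold = 0.5`,
#' `n_val = 5000`, `cv_folds = 10`, `seed = 1`, all methods, both penalty
#' rules, all recalibration options. Unknown keys are rejected.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param overrides named list applied on top of the file contents.
#' @return a validated `scenario_config` list.
#' @export
load_scenario_config <- function(path, overrides = list()) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  raw <- as.list(raw)
  # YAML 1.1 implicit typing turns the bare key `n` into the boolean FALSE
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  scenario_config(utils::modifyList(raw, overrides))
}

#' @param config named list of settings.
#' @rdname load_scenario_config
#' @export
scenario_config <- function(config) {
  defaults <- list(mechanism = NULL, n = NULL, miss = NULL, m = 10L,
                   cycles = 5L, donors = 5L, reps = 1L, B = 100L,
                   threshold = 0.5, n_val = 5000L, cv_folds = 10L, seed = 1L,
                   methods = c("FULL", "TrueC", "BBeF", "BLaF", "SepAv",
                               "SepAvF", "Stack", "StackW"),
                   penalty_rules = c("1se", "optimal"),
                   recalibrations = c("none", "score", "refit"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$mechanism) || !cfg$mechanism %in% c("one", "two"))
    stop("config field 'mechanism' must be \"one\" or \"two\"")
  if (is.null(cfg$n) || cfg$n < 1) stop("config field 'n' must be >= 1")
  if (is.null(cfg$miss) || cfg$miss <= 0 || cfg$miss >= 1)
    stop("config field 'miss' must be in (0, 1)")
  if (cfg$reps < 1) stop("config field 'reps' must be >= 1")
  if (cfg$m < 2) stop("config field 'm' must be >= 2")
  if (cfg$B < 1) stop("config field 'B' must be >= 1")
  if (cfg$threshold <= 0 || cfg$threshold > 1)
    stop("config field 'threshold' must be in (0, 1]")
  bad <- setdiff(cfg$methods, defaults$methods)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$penalty_rules, c("1se", "optimal"))
  if (length(bad)) stop("unknown penalty rules: ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$recalibrations, c("none", "score", "refit"))
  if (length(bad)) stop("unknown recalibrations: ", paste(bad, collapse = ", "))
  structure(cfg, class = "scenario_config")
}

#' @param config a `scenario_config`.
#' @rdname load_scenario_config
#' @export
save_scenario_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Fit the requested method variants on one imputation set
#'
#' Runs every method variant of the configuration on one `imputation_set`,
#' sharing work where the variants allow it: the per-completion CV fits are
#' computed once for the SepAv family (both penalty rules read the same
#' curves), each stacked CV once per weighting, and one CV per bootstrap
#' resample serves both lasso inclusion-frequency bases. Convergence
#' failures (e.g. separation inside backward elimination) are caught per
#' variant and reported in the `failures` element.
#'
#' @param imps an `imputation_set`.
#' @param config a [scenario_config()] (its `n`/`miss`/`reps` fields are not
#'   used here).
#' @param mech mechanism (needed for `TrueC`).
#' @param seed master seed for fold assignments and bootstrap draws.
#' @return list with `models` (named list of [pooled_model()]) and
#'   `failures` (named character vector of failure messages).
#' @export
fit_variants <- function(imps, config, mech = NULL, seed = 1L) {
  models <- list()
  failures <- character()
  add <- function(name, expr) {
    res <- tryCatch(expr, mivarsel_convergence_error = function(e) e)
    if (inherits(res, "condition")) failures[[name]] <<- conditionMessage(res)
    else models[[name]] <<- res
    invisible(NULL)
  }
  rules <- config$penalty_rules
  recals <- setdiff(config$recalibrations, "none")
  want <- function(mm) mm %in% config$methods

  if (want("FULL")) add("FULL", fit_reference(imps, "FULL"))
  if (want("TrueC")) {
    if (is.null(mech)) stop("TrueC requires the mechanism")
    add("TrueC", fit_reference(imps, "TrueC", true_idx = mech$true_idx))
  }
  if (want("BBeF")) {
    add("BBeF", {
      fr <- bootstrap_inclusion(imps, B = config$B, base = "aic_backward",
                                seed = child_seed(seed, "bbef"),
                                k = config$cv_folds)
      select_by_frequency(fr, imps, threshold = config$threshold,
                          method = "BBeF")
    })
  }
  if (want("BLaF")) {
    frs <- bootstrap_inclusion_lasso(imps, B = config$B,
                                     seed = child_seed(seed, "blaf"),
                                     k = config$cv_folds)
    for (rule in rules) {
      fr <- if (rule == "1se") frs$lasso_1se else frs$lasso_opt
      add(variant_name("BLaF", rule, "none"),
          select_by_frequency(fr, imps, threshold = config$threshold,
                              method = "BLaF"))
    }
  }
  if (want("SepAv") || want("SepAvF")) {
    cvs <- sepav_cvs(imps, seed = child_seed(seed, "sepav"),
                     k = config$cv_folds)
    for (mm in intersect(c("SepAv", "SepAvF"), config$methods)) {
      maj <- mm == "SepAvF"
      for (rule in rules) {
        base <- sepav_pool(cvs, rule, maj, imps)
        add(variant_name(mm, rule, "none"), base)
        if (rule == "1se") {
          for (rc in recals)
            add(variant_name(mm, rule, rc), apply_recal(base, rc, imps))
        }
      }
    }
  }
  for (mm in intersect(c("Stack", "StackW"), config$methods)) {
    wgt <- if (mm == "Stack") "uniform" else "missingness"
    st <- make_stack(imps, wgt)
    cv <- lasso_cv(st$X, st$y, weights = st$row_weight, k = config$cv_folds,
                   group_ids = st$subject_id, seed = child_seed(seed, mm))
    for (rule in rules) {
      base <- stacked_pool(cv, rule, wgt)
      add(variant_name(mm, rule, "none"), base)
      if (rule == "1se") {
        for (rc in recals)
          add(variant_name(mm, rule, rc), apply_recal(base, rc, st))
      }
    }
  }
  list(models = models, failures = failures)
}

apply_recal <- function(model, rc, data) {
  if (rc == "score") recalibrate_by_score(model, data)
  else recalibrate_by_refit(model, data)
}

variant_name <- function(method, rule, recal) {
  nm <- if (rule == "optimal") paste0(method, "o") else method
  if (recal != "none") nm <- paste0(nm, "-", recal)
  nm
}

# one CV per bootstrap resample feeds both lasso inclusion bases
bootstrap_inclusion_lasso <- function(imps, B, seed = NULL, k = 10) {
  n <- length(imps$source$y)
  p <- ncol(imps$source$X)
  f1 <- matrix(FALSE, imps$m * B, p)
  fo <- matrix(FALSE, imps$m * B, p)
  r <- 0L
  for (kk in seq_len(imps$m)) {
    dat <- imps$completed[[kk]]
    for (b in seq_len(B)) {
      if (!is.null(seed)) set.seed(child_seed(seed, "boot", kk, b))
      idx <- sample.int(n, n, replace = TRUE)
      cv <- lasso_cv(dat$X[idx, , drop = FALSE], dat$y[idx], k = k,
                     seed = if (is.null(seed)) NULL
                            else child_seed(seed, "bootcv", kk, b))
      r <- r + 1L
      f1[r, which(cv$coef_1se[-1] != 0)] <- TRUE
      fo[r, which(cv$coef_opt[-1] != 0)] <- TRUE
    }
  }
  list(lasso_1se = structure(list(freq = colMeans(f1), fits = f1,
                                  failures = 0L, B = B, m = imps$m,
                                  base = "lasso_1se"),
                             class = "inclusion_freq"),
       lasso_opt = structure(list(freq = colMeans(fo), fits = fo,
                                  failures = 0L, B = B, m = imps$m,
                                  base = "lasso_opt"),
                             class = "inclusion_freq"))
}

#' Run a full simulation scenario
#'
#' For each replicate: generate a complete dataset from the mechanism,
#' impose missing-at-random missingness, impute by chained equations, fit
#' every requested method variant, and evaluate each pooled model on a
#' fresh, fully observed validation set of `n_val` subjects. All stages
#' consume child seeds of the master seed, so the run is reproducible and
#' replicate results are order-independent.
#'
#' @param config a [scenario_config()].
#' @param out optional CSV path for the tidy records ([write_results()]).
#' @param progress print a line per replicate.
#' @return tidy data frame: one row per replicate x method variant, with
#'   performance fields, variant labels, replicate id and failure flags
#'   (failed variants keep their row with `NA` metrics).
#' @export
run_scenario <- function(config, out = NULL, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  mech <- build_mechanism(config$mechanism)
  rows <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    master <- config$seed
    dat <- generate_complete(mech, config$n,
                             seed = child_seed(master, "gen", r))
    inc <- impose_mar(dat, mech, config$miss,
                      seed = child_seed(master, "mar", r))
    imps <- impute_chained(inc, m = config$m, cycles = config$cycles,
                           donors = config$donors,
                           seed = child_seed(master, "imp", r))
    fv <- fit_variants(imps, config, mech = mech,
                       seed = child_seed(master, "fit", r))
    val <- generate_complete(mech, config$n_val,
                             seed = child_seed(master, "val", r))
    recs <- lapply(names(fv$models), function(nm) {
      pr <- evaluate_external(fv$models[[nm]], mech, val = val)
      data.frame(replicate = r, variant = nm, method = pr$method,
                 penalty_rule = pr$penalty_rule,
                 recalibration = pr$recalibration,
                 auc = pr$auc, brier = pr$brier,
                 n_true_selected = pr$n_true_selected,
                 n_noise_selected = pr$n_noise_selected,
                 n_selected = pr$n_selected,
                 epv = events_per_variable(dat$y, mech$p),
                 failed = FALSE, failure = "")
    })
    fails <- lapply(names(fv$failures), function(nm) {
      data.frame(replicate = r, variant = nm, method = NA_character_,
                 penalty_rule = NA_character_, recalibration = NA_character_,
                 auc = NA_real_, brier = NA_real_,
                 n_true_selected = NA_integer_, n_noise_selected = NA_integer_,
                 n_selected = NA_integer_,
                 epv = events_per_variable(dat$y, mech$p),
                 failed = TRUE, failure = fv$failures[[nm]])
    })
    rows[[r]] <- do.call(rbind, c(recs, fails))
    if (progress)
      cat(sprintf("replicate %d/%d done (%d variants, %d failures)\n",
                  r, config$reps, length(fv$models), length(fv$failures)))
  }
  records <- do.call(rbind, rows)
  if (!is.null(out)) write_results(records, out)
  records
}

result_columns <- c("replicate", "variant", "method", "penalty_rule",
                    "recalibration", "auc", "brier", "n_true_selected",
                    "n_noise_selected", "n_selected", "epv", "failed",
                    "failure")

#' Write / read tidy replicate records as CSV
#'
#' Deterministic column order; an empty record set yields a header-only file.
#' @param records data frame of replicate records.
#' @param path CSV path.
#' @return `path` (write) or the records data frame (read).
#' @export
write_results <- function(records, path) {
  if (nrow(records) == 0) {
    records <- records[, intersect(result_columns, names(records)),
                       drop = FALSE]
  } else {
    missing_cols <- setdiff(result_columns, names(records))
    for (mc in missing_cols) records[[mc]] <- NA
    records <- records[, result_columns, drop = FALSE]
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(failure = "character"))
  df$failed <- as.logical(df$failed)
  df
}
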