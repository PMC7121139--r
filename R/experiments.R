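#' Define the silencing sweep grid
#'
#' Cross product of silencing targets and fractions, each condition run for
#' a number of repetitions with deterministic per-condition seeds, plus
#' (optionally) unsilenced control repetitions. The study grid is 4 targets
#' x 6 fractions x 5 repetitions + 5 controls = 125 runs.
#'
#' @param targets Character vector of silencing targets.
#' @param fractions Numeric vector of silenced fractions (all > 0).
#' @param repetitions Repetitions per condition (default 5).
#' @param include_control Add `repetitions` control runs (target `"none"`,
#'   fraction 0).
#' @return A `sweep_grid` list.
#' @export
sweep_grid <- function(targets = c("whole", "leader", "excitatory",
                                   "interneuron"),
                       fractions = c(0.01, 0.1, 0.2, 0.3, 0.5, 0.8),
                       repetitions = 5,
                       include_control = TRUE) {
  targets <- match.arg(targets, c("whole", "leader", "excitatory",
                                  "interneuron"), several.ok = TRUE)
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must lie in (0, 1]")
  structure(list(targets = targets, fractions = fractions,
                 repetitions = as.integer(repetitions),
                 include_control = include_control),
            class = "sweep_grid")
}

#' Enumerate the conditions of a sweep grid
#'
#' @param grid A [sweep_grid()].
#' @return Data.frame `target`, `fraction`, `rep` with one row per run.
#' @export
sweep_conditions <- function(grid) {
  cond <- expand.grid(rep = seq_len(grid$repetitions),
                      fraction = grid$fractions,
                      target = grid$targets,
                      stringsAsFactors = FALSE)
  if (grid$include_control)
    cond <- rbind(data.frame(rep = seq_len(grid$repetitions), fraction = 0,
                             target = "none"),
                  cond)
  cond[, c("target", "fraction", "rep")]
}

# Metrics of one finished run, as one tidy row.
run_record <- function(result, target, fraction, rep, seed,
                       bands = default_bands()) {
  rates <- per_neuron_rates(result$raster)
  summ <- population_rates(rates)
  g <- function(pop, col) {
    v <- summ[[col]][summ$population == pop]
    if (length(v)) v else NA_real_
  }
  psd <- estimate_psd(result, column = "vm_sum")
  bp <- vapply(bands$name, function(b) band_power(psd, b, bands), numeric(1))
  names(bp) <- paste0("power_", bands$name)
  cbind(
    data.frame(target = target, fraction = fraction, rep = rep, seed = seed,
               rate_mean_excitatory = g("excitatory", "mean_hz"),
               rate_median_excitatory = g("excitatory", "median_hz"),
               rate_mean_leader = g("leader", "mean_hz"),
               rate_mean_interneuron = g("interneuron", "mean_hz"),
               rate_mean_whole = g("all", "mean_hz")),
    as.data.frame(as.list(bp)),
    data.frame(synchrony = synchrony_index(result$raster)))
}

#' Run a silencing sweep
#'
#' For every (target, fraction, repetition) of the grid, silences the
#' requested pool, simulates, and summarizes the run into one record:
#' per-population mean/median firing rates, band powers of the summed
#' membrane potential, and the synchrony index.
#'
#' Seeding: wiring and the initial state depend only on
#' (`master_seed`, repetition), so within a repetition every condition
#' perturbs the *same* realized network and start state (matched-control
#' design); the silencing draw depends on (`master_seed`, target, fraction,
#' repetition). Re-running with the same seeds reproduces every record
#' bit-identically.
#'
#' If `out_dir` is given, each finished record is written to a CSV named by
#' a fingerprint of (condition, seeds, config) and skipped on re-run, so an
#' interrupted sweep resumes where it stopped. A failed run is recorded
#' with `ok = FALSE` and its error message, never dropped.
#'
#' @param config Base [network_config()] (unsilenced).
#' @param grid A [sweep_grid()].
#' @param master_seed Master seed (default `config$seed`).
#' @param out_dir Optional directory for resumable per-run records.
#' @param bands Band table for the spectral summaries.
#' @param verbose Print one line per run.
#' @return Data.frame of run records (`target`, `fraction`, `rep`, `seed`,
#'   rate and power columns, `synchrony`, `ok`, `error`).
#' @export
run_sweep <- function(config, grid, master_seed = config$seed,
                      out_dir = NULL, bands = default_bands(),
                      verbose = FALSE) {
  cond <- sweep_conditions(grid)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cfg_fp <- object_fingerprint(unclass(config))
  networks <- new.env(parent = emptyenv())
  records <- vector("list", nrow(cond))
  for (r in seq_len(nrow(cond))) {
    target <- cond$target[r]; fraction <- cond$fraction[r]; rep <- cond$rep[r]
    run_seed <- derive_seed(master_seed, "run", target, format(fraction), rep)
    fp <- NULL
    if (!is.null(out_dir)) {
      fp <- file.path(out_dir, sprintf("run-%s-%s.csv",
                                       object_fingerprint(list(target, fraction, rep, run_seed)),
                                       cfg_fp))
      if (file.exists(fp)) {
        records[[r]] <- utils::read.csv(fp)
        if (verbose) message("skip (done): ", target, " ", fraction, " rep ", rep)
        next
      }
    }
    rec <- tryCatch({
      key <- paste0("rep", rep)
      if (is.null(networks[[key]])) {
        cfg_rep <- config
        cfg_rep$seed <- derive_seed(master_seed, "net", rep)
        networks[[key]] <- build_network(cfg_rep)
      }
      net <- networks[[key]]
      if (target != "none" && fraction > 0) {
        spec <- silencing_spec(target, fraction, seed =
                                 derive_seed(master_seed, "sil", target,
                                             format(fraction), rep))
        net <- silence_network(net, spec)
      }
      res <- run_simulation(net, config,
                            seed = derive_seed(master_seed, "init", rep))
      out <- run_record(res, target, fraction, rep, run_seed, bands)
      out$ok <- TRUE
      out$error <- ""
      out
    }, error = function(e) {
      data.frame(target = target, fraction = fraction, rep = rep,
                 seed = run_seed, ok = FALSE, error = conditionMessage(e))
    })
    if (verbose) message(sprintf("%s fraction=%g rep=%d: %s", target,
                                 fraction, rep,
                                 if (isTRUE(rec$ok)) "ok" else "FAILED"))
    if (!is.null(fp) && isTRUE(rec$ok)) utils::write.csv(rec, fp, row.names = FALSE)
    records[[r]] <- rec
  }
  do.call(rbind_fill, list(records))
}

# rbind data.frames with possibly different columns (failed runs carry
# fewer columns than successful ones).
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  }))
}

#' Pearson correlation of silenced fraction vs a response
#'
#' Over all repetitions of one silencing target, correlates the silenced
#' fraction with a response column of the sweep records (two-sided p from
#' the t distribution with n - 2 df). Control records (fraction 0) are
#' excluded unless `include_control = TRUE`.
#'
#' @param records Sweep records from [run_sweep()] (or synthetic ones).
#' @param target Silencing target to subset.
#' @param response Response column name (e.g. `"rate_mean_excitatory"`,
#'   `"power_gamma"`, or `"response"` for synthetic records).
#' @param include_control Include fraction-0 control records.
#' @return List `r`, `p`, `n`, `target`, `response`; `r`/`p` are `NA` with
#'   a `reason` when either variable has zero variance.
#' @export
correlate_fraction <- function(records, target, response,
                               include_control = FALSE) {
  d <- records[isTRUE_or_na(records$ok) & records$target == target, ]
  if (include_control) {
    ctrl <- records[isTRUE_or_na(records$ok) & records$target == "none", ]
    d <- rbind(d, ctrl)
  }
  x <- d$fraction
  y <- d[[response]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3)
    stop("need records at >= 3 distinct fractions for target '", target, "'")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), target = target,
                response = response, reason = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       target = target, response = response)
}

isTRUE_or_na <- function(ok) if (is.null(ok)) TRUE else (is.na(ok) | ok)

#' Two-way ANOVA with Tukey post hoc over sweep records
#'
#' Fits `response ~ factor(fraction) * factor(target)` over the silenced
#' records, reports the ANOVA table (exact F tests for a balanced grid;
#' type-II sums of squares via `car::Anova` when unbalanced) and Tukey HSD
#' comparisons of cell means for each term.
#'
#' @param records Sweep records.
#' @param response Response column name.
#' @param include_control Include fraction-0 controls as a fraction level.
#' @return A `stats_report`: list with `anova` (data.frame `term`, `df`,
#'   `sumsq`, `statistic`, `p_value`), `tukey` (list of data.frames), and
#'   `balanced`.
#' @export
anova_tukey <- function(records, response, include_control = FALSE) {
  d <- records[isTRUE_or_na(records$ok), ]
  if (!include_control) d <- d[d$target != "none", ]
  d <- d[is.finite(d[[response]]), ]
  d$f_fraction <- factor(d$fraction)
  d$f_target <- factor(d$target)
  if (nlevels(d$f_fraction) < 2) stop("factor 'fraction' has fewer than 2 levels")
  if (nlevels(d$f_target) < 2) stop("factor 'target' has fewer than 2 levels")
  d$.y <- d[[response]]
  cells <- table(d$f_fraction, d$f_target)
  balanced <- length(unique(as.vector(cells))) == 1 && all(cells > 0)
  fit <- stats::aov(.y ~ f_fraction * f_target, data = d)
  if (balanced) {
    tab <- summary(fit)[[1]]
    an <- data.frame(term = trimws(rownames(tab)), df = tab[["Df"]],
                     sumsq = tab[["Sum Sq"]], statistic = tab[["F value"]],
                     p_value = tab[["Pr(>F)"]], row.names = NULL)
  } else {
    tab <- car::Anova(stats::lm(.y ~ f_fraction * f_target, data = d),
                      type = 2)
    an <- data.frame(term = trimws(rownames(tab)), df = tab[["Df"]],
                     sumsq = tab[["Sum Sq"]], statistic = tab[["F value"]],
                     p_value = tab[["Pr(>F)"]], row.names = NULL)
  }
  # a degenerate response (all values identical) carries no effect: the
  # sums of squares are numerical fuzz and the F ratio is meaningless
  if (stats::var(d$.y) < .Machine$double.eps^0.5 * max(1, mean(d$.y)^2)) {
    not_resid <- an$term != "Residuals"
    an$statistic[not_resid] <- 0
    an$p_value[not_resid] <- 1
  }
  an$statistic[is.nan(an$statistic)] <- 0
  tk <- tryCatch(
    lapply(stats::TukeyHSD(fit), function(m)
      data.frame(comparison = rownames(m), diff = m[, "diff"],
                 lwr = m[, "lwr"], upr = m[, "upr"],
                 p_adj = m[, "p adj"], row.names = NULL)),
    error = function(e) list())
  structure(list(anova = an, tukey = tk, balanced = balanced,
                 response = response, n = nrow(d)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> response '%s', n = %d (%s design)\n",
              x$response, x$n, if (x$balanced) "balanced" else "unbalanced"))
  print(x$anova, digits = 4)
  invisible(x)
}
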