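## Experiment orchestration: one factorial condition at a time
## (simulate -> filter -> inject missing data -> estimate -> score), and
## desk-scale presets that regenerate each comparison figure's table.

#' Run one experimental condition
#'
#' Simulates a character matrix on the model tree, applies the character
#' filtration scheme and the missing-data operation, estimates the tree
#' with the requested method(s), and scores each estimate against the
#' model tree by Robinson-Foulds distance and rescaled error. Bayesian
#' runs are scored through the majority-rule consensus of the posterior;
#' parsimony runs through both the averaged and the consensus distance of
#' the equally-optimal set (the averaged one fills the `rf`/`error_pct`
#' columns).
#'
#' @param tree Rooted binary model `phylo` with branch lengths (and fossil
#'   flags if fossil masking is requested).
#' @param mean_rate Expected changes per character over the whole tree.
#' @param rate_mode `"single"` or `"per_character"`.
#' @param gamma_shape Shape for the simulating rate draw; `Inf` pins the
#'   rate at `mean_rate` exactly (grid conditions).
#' @param n_characters Characters to simulate before filtering.
#' @param filtration Character acquisition scheme (see [filter_matrix()]);
#'   the matching ascertainment correction is applied automatically
#'   (`unfiltered` -> Mk, `variable_only` -> Mkv,
#'   `parsimony_informative_only` -> Mk-parsinf).
#' @param missing Missing-data operation: `list(type = "none")`,
#'   `list(type = "mask_fossil", fraction = )`, or
#'   `list(type = "delete_rate_class", class = , fraction = )`.
#' @param methods Subset of `c("bayes", "parsimony")`.
#' @param replicate Replicate index (recorded in the output).
#' @param seed Integer seed; sub-seeds for simulation, masking and the two
#'   estimators are derived from it, so a (condition, replicate, seed)
#'   triple reproduces its record exactly.
#' @param bayes_control Overrides for [mk_bayes()]: `n_generations`,
#'   `sample_every`, `burnin_fraction`, `params`, ...
#' @param parsimony_control Overrides for [mk_parsimony()]:
#'   `n_replicates`, `max_trees`, `swap`.
#' @return A data frame with one row per method. Estimation failures do not
#'   abort a batch: the affected row carries `NA` scores and the error
#'   message in `status`.
#' @export
run_condition <- function(tree, mean_rate = 1,
                          rate_mode = c("single", "per_character"),
                          gamma_shape = Inf, n_characters = 350,
                          filtration = c("variable_only", "unfiltered",
                                         "parsimony_informative_only"),
                          missing = list(type = "none"),
                          methods = c("bayes", "parsimony"),
                          replicate = 1L, seed = 1L,
                          bayes_control = list(),
                          parsimony_control = list()) {
  rate_mode <- match.arg(rate_mode)
  filtration <- match.arg(filtration)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(tree, "phylo"))
  seed <- as.integer(seed)

  cfg <- sim_config(n_characters = n_characters, rate_mode = rate_mode,
                    gamma_shape = gamma_shape, mean_rate = mean_rate,
                    seed = seed)
  x <- simulate_characters(tree, cfg)
  x <- filter_matrix(x, filtration)
  mtype <- missing$type %||% "none"
  if (mtype == "mask_fossil") {
    x <- mask_fossil_cells(x, tree, missing$fraction, seed = seed + 1L)
  } else if (mtype == "delete_rate_class") {
    x <- delete_rate_class(x, missing$class, missing$fraction,
                           seed = seed + 1L)
  } else if (mtype != "none") {
    stop("unknown missing-data type: ", mtype)
  }
  if (ncol(x$states) == 0L)
    stop("condition produced an empty matrix")

  asc <- switch(filtration, unfiltered = "none",
                variable_only = "variable",
                parsimony_informative_only = "parsimony_informative")
  n_leaf <- length(tree$tip.label)
  base <- data.frame(mean_rate = mean_rate, rate_mode = rate_mode,
                     sim_gamma_shape = gamma_shape,
                     n_characters = n_characters,
                     n_characters_used = ncol(x$states),
                     filtration = filtration, missing_type = mtype,
                     missing_fraction = missing$fraction %||% NA_real_,
                     missing_class = missing$class %||% NA_character_,
                     replicate = as.integer(replicate), seed = seed,
                     stringsAsFactors = FALSE)
  rows <- list()

  if ("parsimony" %in% methods || "bayes" %in% methods) {
    # random-addition tree reused as the MCMC starting point
    start <- random_addition_tree(x, seed = seed + 4L)
  }
  failed_row <- function(method, t0, e) cbind(base, data.frame(
    method = method, rf = NA_real_, error_pct = NA_real_,
    rf_mean = NA_real_, rf_consensus = NA_real_,
    error_consensus_pct = NA_real_, statistic = NA_real_,
    n_trees = NA_integer_, seconds = proc.time()[["elapsed"]] - t0,
    status = paste("error:", conditionMessage(e)),
    stringsAsFactors = FALSE))
  if ("bayes" %in% methods) {
    pc <- bayes_control
    params <- pc$params %||% mk_params(
      ascertainment = asc,
      gamma_shape = if (rate_mode == "per_character") 1.0 else NULL)
    t0 <- proc.time()[["elapsed"]]
    rows$bayes <- tryCatch({
      fit <- mk_bayes(x, params = params,
                      n_generations = pc$n_generations %||% 20000L,
                      sample_every = pc$sample_every %||% 20L,
                      burnin_fraction = pc$burnin_fraction %||% 0.25,
                      start_tree = start, seed = seed + 2L)
      post <- summarize_posterior(fit)
      rf <- rf_distance(post$consensus, tree)
      cbind(base, data.frame(
        method = "bayes", rf = rf,
        error_pct = rescaled_error(rf, n_leaf),
        rf_mean = NA_real_, rf_consensus = rf,
        error_consensus_pct = rescaled_error(rf, n_leaf),
        statistic = as.numeric(logLik(fit)), n_trees = post$n_trees,
        seconds = proc.time()[["elapsed"]] - t0, status = "ok",
        stringsAsFactors = FALSE))
    }, error = function(e) failed_row("bayes", t0, e))
  }
  if ("parsimony" %in% methods) {
    pc <- parsimony_control
    t0 <- proc.time()[["elapsed"]]
    rows$parsimony <- tryCatch({
      fit <- mk_parsimony(x, n_replicates = pc$n_replicates %||% 5L,
                          swap = pc$swap %||% "tbr",
                          max_trees = pc$max_trees %||% 100L,
                          seed = seed + 3L)
      sc <- score_solution_set(fit, tree)
      cbind(base, data.frame(
        method = "parsimony", rf = sc$mean_rf,
        error_pct = sc$mean_error_pct,
        rf_mean = sc$mean_rf, rf_consensus = sc$consensus_rf,
        error_consensus_pct = sc$consensus_error_pct,
        statistic = fit$score, n_trees = fit$n_trees,
        seconds = proc.time()[["elapsed"]] - t0, status = "ok",
        stringsAsFactors = FALSE))
    }, error = function(e) failed_row("parsimony", t0, e))
  }
  do.call(rbind, unname(rows))
}

# derive a deterministic sub-seed per (condition index, replicate)
condition_seed <- function(base_seed, cond_idx, replicate) {
  (as.integer(base_seed) * 7919L + cond_idx * 1009L + replicate * 13L) %%
    2147483L + 1L
}

# run a grid of conditions x replicates; conditions is a list of lists of
# run_condition() arguments
run_grid <- function(tree, conditions, n_replicates, base_seed,
                     bayes_control = list(), parsimony_control = list(),
                     verbose = FALSE) {
  out <- vector("list", 0L)
  for (ci in seq_along(conditions)) {
    for (rep in seq_len(n_replicates)) {
      args <- c(list(tree = tree), conditions[[ci]],
                list(replicate = rep,
                     seed = condition_seed(base_seed, ci, rep),
                     bayes_control = bayes_control,
                     parsimony_control = parsimony_control))
      if (verbose)
        message("condition ", ci, "/", length(conditions),
                " replicate ", rep)
      out[[length(out) + 1L]] <- do.call(run_condition, args)
    }
  }
  do.call(rbind, out)
}

#' Rerun one figure's comparison at desk scale
#'
#' Presets covering the study's comparisons: `fig3` (single-rate grid,
#' with and without fossil masking), `fig4` (per-character rate
#' heterogeneity), `fig5` (deleting one-third of each rate tertile),
#' `fig6` (350- vs 1000-character data sets), `figS1` (the three Mk
#' ascertainment parameterizations on matched data), and `figS2`
#' (averaged vs consensus scoring of parsimony solution sets). Every
#' preset emits the tidy per-replicate table plus the mean/sd/se summary
#' needed to redraw the figure; the presets shrink the original design
#' (20 taxa, short chains, few replicates by default) while keeping its
#' factorial structure.
#'
#' @param figure One of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`, `"figS1"`,
#'   `"figS2"`.
#' @param tree Model tree; generated by [generate_model_tree()] when
#'   `NULL`.
#' @param n_taxa Taxa for the generated tree (default 20).
#' @param rate_grid Mean-rate grid (expected changes per character).
#' @param n_characters Characters per data set (except `fig6`, which uses
#'   350 and 1000).
#' @param n_replicates Replicates per condition.
#' @param base_seed Base seed for the deterministic sub-seed policy.
#' @param bayes_control,parsimony_control Engine overrides (see
#'   [run_condition()]).
#' @param verbose Print progress messages.
#' @return An object of class `mk_experiment`: list with `results` (per
#'   replicate), `summary` (per condition), `tree`, `figure`, `config`.
#' @export
replicate_figure <- function(figure = c("fig3", "fig4", "fig5", "fig6",
                                        "figS1", "figS2"),
                             tree = NULL, n_taxa = 20,
                             rate_grid = c(0.1, 0.25, 0.5, 1, 2, 5, 10),
                             n_characters = 350, n_replicates = 10,
                             base_seed = 1L,
                             bayes_control = list(),
                             parsimony_control = list(),
                             verbose = FALSE) {
  figure <- match.arg(figure)
  if (is.null(tree))
    tree <- generate_model_tree(n_taxa, seed = base_seed)
  single <- function(r, ...) list(mean_rate = r, rate_mode = "single",
                                  gamma_shape = Inf,
                                  n_characters = n_characters, ...)
  hetero <- function(r, ...) list(mean_rate = r, rate_mode = "per_character",
                                  gamma_shape = 1,
                                  n_characters = n_characters, ...)
  conds <- switch(figure,
    fig3 = c(lapply(rate_grid, single),
             lapply(rate_grid, function(r)
               single(r, missing = list(type = "mask_fossil",
                                        fraction = 0.75)))),
    fig4 = lapply(rate_grid, hetero),
    fig5 = {
      dels <- c(list(list(type = "none")),
                lapply(c("slow", "intermediate", "fast"), function(cl)
                  list(type = "delete_rate_class", class = cl,
                       fraction = 1 / 3)))
      unlist(lapply(rate_grid, function(r)
        lapply(dels, function(d) hetero(r, missing = d))), recursive = FALSE)
    },
    fig6 = unlist(lapply(c(350, 1000), function(nc)
      lapply(rate_grid, function(r) {
        cnd <- single(r); cnd$n_characters <- nc; cnd
      })), recursive = FALSE),
    figS1 = unlist(lapply(rate_grid, function(r) lapply(
      c("unfiltered", "variable_only", "parsimony_informative_only"),
      function(f) single(r, filtration = f, methods = "bayes"))),
      recursive = FALSE),
    figS2 = lapply(rate_grid, function(r) single(r, methods = "parsimony"))
  )
  res <- run_grid(tree, conds, n_replicates, base_seed,
                  bayes_control = bayes_control,
                  parsimony_control = parsimony_control, verbose = verbose)
  structure(list(results = res, summary = summarize_experiment(res),
                 tree = tree, figure = figure,
                 config = list(n_taxa = length(tree$tip.label),
                               rate_grid = rate_grid,
                               n_characters = n_characters,
                               n_replicates = n_replicates,
                               base_seed = base_seed)),
            class = "mk_experiment")
}

#' Aggregate per-replicate results into a per-condition summary
#'
#' @param results The per-replicate data frame from [run_condition()] /
#'   [replicate_figure()].
#' @return Data frame with mean, sd and standard error of the rescaled
#'   error per (condition, method), plus the consensus-scored means.
#' @export
summarize_experiment <- function(results) {
  keys <- c("method", "mean_rate", "rate_mode", "n_characters",
            "filtration", "missing_type", "missing_fraction",
            "missing_class")
  if ("status" %in% names(results)) results <- results[results$status == "ok", ]
  keys <- intersect(keys, names(results))
  gd <- results[keys]
  gd[] <- lapply(gd, function(col) ifelse(is.na(col), "none", as.character(col)))
  grp <- interaction(gd, drop = TRUE)
  agg <- lapply(split(results, grp), function(d) {
    cbind(d[1L, keys, drop = FALSE],
          data.frame(n = nrow(d),
                     mean_error_pct = mean(d$error_pct),
                     sd_error_pct = sd(d$error_pct),
                     se_error_pct = sd(d$error_pct) / sqrt(nrow(d)),
                     mean_consensus_error_pct = mean(d$error_consensus_pct)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$method, out$mean_rate), ]
}

#' @export
print.mk_experiment <- function(x, ...) {
  cat("Desk-scale rerun of", x$figure, "comparison:",
      x$config$n_taxa, "taxa,", x$config$n_replicates,
      "replicates per condition\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.mk_experiment <- function(x, ...) {
  s <- x$summary
  if (!length(unique(s$mean_rate)) > 1) {
    barplot(s$mean_error_pct, names.arg = paste(s$method),
            ylab = "rescaled error (%)")
    return(invisible(x))
  }
  conds <- split(s, interaction(s[setdiff(names(s),
    c("mean_rate", "n", "mean_error_pct", "sd_error_pct", "se_error_pct",
      "mean_consensus_error_pct"))], drop = TRUE))
  cols <- seq_along(conds)
  plot(NA, xlim = range(s$mean_rate), ylim = c(0, max(s$mean_error_pct) * 1.1),
       log = "x", xlab = "expected changes per character",
       ylab = "rescaled error (%)", main = x$figure)
  for (i in seq_along(conds)) {
    d <- conds[[i]][order(conds[[i]]$mean_rate), ]
    lines(d$mean_rate, d$mean_error_pct, type = "b", col = cols[i], pch = 16)
  }
  legend("topleft", legend = names(conds), col = cols, lty = 1, pch = 16,
         cex = 0.7, bty = "n")
  invisible(x)
}
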