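#' Run the full Rasch scale-validation pipeline
#'
#' Orchestrates the complete validation workflow for a candidate symptom
#' scale on one dataset:
#'
#' 1. split the persons into disjoint calibration and validation samples;
#' 2. parallel analysis of the full item set in both samples;
#' 3. iterative item elimination on the calibration sample, one item at a
#'    time with re-estimation after every removal. At each step the model is
#'    refitted and both pathologies are diagnosed. A Q3-flagged pair of
#'    locally dependent items takes precedence: response dependence
#'    contaminates every item's fit statistic (the model-based residual
#'    variances assume local independence), so the pair is resolved — by
#'    removing the member with the larger mean absolute residual correlation
#'    against all other items (tie-break: worse absolute log infit) — before
#'    any infit value is trusted. Otherwise the single item whose infit mean
#'    square lies furthest outside the acceptance band (largest absolute log
#'    mean square) is removed. With `confirm_with_validation = TRUE` (the
#'    default) an elimination additionally requires the same finding in the
#'    validation sample fitted on the same item set — the same pair flagged,
#'    or the same item outside the band on the same side — so that single-
#'    sample sampling noise does not discard sound items;
#' 4. parallel analysis of the retained set;
#' 5. DIF assessment of the retained items for each requested covariate —
#'    flagged items are reported, never auto-removed, and scale-level DIF is
#'    summarised by tau-squared;
#' 6. reliability (Cronbach's alpha, PSI) of the initial set, the retained
#'    set, and any user-named subsets;
#' 7. the elimination procedure is re-run with the sample roles swapped and
#'    per-item agreement with the calibration-driven decisions is reported;
#'    the swapped run never changes the retained set.
#'
#' @param data a [response_matrix()] with at least `2 * n_per_sample`
#'   persons.
#' @param config a [validation_config()].
#' @return An object of class `rasch_validation`: list with
#'   `elimination_log` (data frame: stage, item, reason, statistic),
#'   `retained_items`, per-sample `diagnostics` (parallel analyses, final
#'   fit, infit and Q3 tables), `dif` (per covariate, per sample),
#'   `reliability` (per sample: initial, retained, subsets), `agreement`
#'   (validation re-check), `wright_map_data`, `split`, and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_responses(sim_config(n_persons = 600, seed = 7))
#' res <- rasch_validate(sim, validation_config(n_per_sample = 300,
#'                                              pa_sims = 200, seed = 7))
#' print(res)
#' }
#' @export
rasch_validate <- function(data, config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  if (!inherits(data, "response_matrix")) data <- response_matrix(data)
  sub_seed <- function(off) (config$seed + 7919L * off) %% .Machine$integer.max
  split <- split_samples(data, config$n_per_sample, seed = config$seed)
  cal <- split$calibration
  val <- split$validation
  all_items <- colnames(cal)

  pa_initial <- list(
    calibration = parallel_analysis(cal, config$pa_sims, seed = sub_seed(1L)),
    validation = parallel_analysis(val, config$pa_sims, seed = sub_seed(2L)))

  confirm <- if (isTRUE(config$confirm_with_validation)) val else NULL
  elim_cal <- run_elimination(cal, config, confirm = confirm)
  retained <- elim_cal$retained

  pa_retained <- list(
    calibration = parallel_analysis(subset_responses(cal, items = retained),
                                    config$pa_sims, seed = sub_seed(3L)),
    validation = parallel_analysis(subset_responses(val, items = retained),
                                   config$pa_sims, seed = sub_seed(4L)))

  dif <- list()
  for (cv in config$dif_covariates) {
    dif[[cv]] <- list(
      calibration = dif_test(subset_responses(cal, items = retained), cv,
                             alpha = config$alpha_level),
      validation = dif_test(subset_responses(val, items = retained), cv,
                            alpha = config$alpha_level))
  }

  rel_side <- function(rm) {
    subsets <- c(list(initial = all_items, retained = retained),
                 config$reliability_subsets)
    lapply(subsets, function(it) {
      tryCatch(scale_reliability(rm, items = it,
                                 alpha_threshold = config$alpha_threshold,
                                 psi_threshold = config$psi_threshold),
               error = function(e) {
                 warning(sprintf("reliability subset skipped: %s",
                                 conditionMessage(e)))
                 NULL
               })
    })
  }
  reliability <- list(calibration = rel_side(cal), validation = rel_side(val))

  # re-run of the elimination procedure with the sample roles swapped
  confirm2 <- if (isTRUE(config$confirm_with_validation)) cal else NULL
  elim_val <- run_elimination(val, config, confirm = confirm2)
  stage_of <- function(log) {
    st <- stats::setNames(log$stage, log$item)
    function(item) if (item %in% names(st)) unname(st[item]) else "retained"
  }
  sc <- stage_of(elim_cal$log); sv <- stage_of(elim_val$log)
  agreement <- data.frame(
    item = all_items,
    calibration = vapply(all_items, sc, ""),
    validation = vapply(all_items, sv, ""),
    row.names = NULL)
  agreement$agree <- agreement$calibration == agreement$validation

  final_fit <- elim_cal$fit
  persons <- ability_wle(final_fit)
  h <- graphics::hist(persons$theta, breaks = "Sturges", plot = FALSE)
  wright_map_data <- list(theta = persons$theta, beta = final_fit$beta,
                          hist_breaks = h$breaks, hist_counts = h$counts)

  structure(list(elimination_log = elim_cal$log,
                 retained_items = retained,
                 diagnostics = list(
                   calibration = list(pa_initial = pa_initial$calibration,
                                      pa_retained = pa_retained$calibration,
                                      fit = final_fit,
                                      infit = elim_cal$infit,
                                      q3 = elim_cal$q3),
                   validation = list(pa_initial = pa_initial$validation,
                                     pa_retained = pa_retained$validation,
                                     fit = elim_val$fit,
                                     infit = elim_val$infit,
                                     q3 = elim_val$q3)),
                 dif = dif,
                 reliability = reliability,
                 agreement = agreement,
                 validation_log = elim_val$log,
                 wright_map_data = wright_map_data,
                 split = list(calibration_idx = split$calibration_idx,
                              validation_idx = split$validation_idx),
                 config = config),
            class = "rasch_validation")
}

# Iterative item elimination on one sample, optionally requiring every
# finding to be confirmed in a second sample fitted on the same item set.
# Returns the log, the retained labels, the final fit and diagnostic tables.
run_elimination <- function(rm, config, confirm = NULL) {
  elog <- data.frame(stage = character(), item = character(),
                     reason = character(), statistic = numeric())
  current <- rm
  confirm_cur <- confirm
  need <- function() {
    if (n_items(current) - 1L < 3L)
      stop_raschval("elimination would leave fewer than 3 items; aborting",
                    class = "raschval_abort", partial_log = elog)
  }
  diagnose <- function(sample) {
    fit <- rasch_cml(sample)
    ab <- ability_wle(fit)
    inf <- item_infit(fit, abilities = ab, bounds = config$infit_bounds)
    q3 <- residual_correlations(fit, abilities = ab,
                                r_threshold = config$q3_threshold,
                                alpha = config$alpha_level)
    list(fit = fit, infit = inf, q3 = q3)
  }
  drop_from <- function(sample, item)
    subset_responses(sample, items = setdiff(colnames(sample), item))
  pair_key <- function(fp) paste(pmin(fp$item_i, fp$item_j),
                                 pmax(fp$item_i, fp$item_j))
  # Each pass removes one item, attributed to the statistic that demands it.
  # A flagged Q3 pair takes precedence over an out-of-band infit: response
  # dependence contaminates the fit statistics of every item (the
  # model-based residual variances assume local independence), so no infit
  # value is trusted for elimination while a dependent pair is present, and
  # removing a pair member as "misfitting" would misattribute the pathology.
  repeat {
    d <- diagnose(current)
    dc <- if (!is.null(confirm_cur)) diagnose(confirm_cur)
    fp <- d$q3$flagged_pairs
    if (!is.null(dc) && nrow(fp)) {
      # confirmation: the same pair must replicate in the other sample with
      # r above threshold and an unadjusted significant p (no familywise
      # control when replicating one specific, pre-identified pair)
      cp <- dc$q3$pairs
      ck <- pair_key(cp)[cp$r > config$q3_threshold &
                           cp$p_raw <= config$alpha_level]
      fp <- fp[pair_key(fp) %in% ck, , drop = FALSE]
    }
    if (nrow(fp) > 0) {
      # local independence: drop the worse member of the strongest pair
      top <- fp[which.max(fp$chi2), ]
      R <- abs(d$q3$pair_correlations)
      diag(R) <- NA
      mq <- rowMeans(R, na.rm = TRUE)
      cand <- c(top$item_i, top$item_j)
      m <- mq[cand]
      drop_item <- if (abs(m[1] - m[2]) > 1e-12) {
        cand[which.max(m)]
      } else {
        lmsq <- abs(log(d$infit$infit_msq[match(cand, d$infit$item)]))
        cand[which.max(lmsq)]
      }
      need()
      elog <- rbind(elog, data.frame(
        stage = "local_dependence", item = drop_item,
        reason = sprintf("residual correlation %.3f with '%s' (Holm p = %.4f)",
                         top$r, setdiff(cand, drop_item), top$p_holm),
        statistic = top$r))
      current <- drop_from(current, drop_item)
      if (!is.null(confirm_cur)) confirm_cur <- drop_from(confirm_cur, drop_item)
      next
    }
    # probabilistic Guttman pattern: drop the worst out-of-band infit
    inf <- d$infit
    out <- which(inf$flagged)
    if (!is.null(dc) && length(out)) {
      # confirmation: the other sample must show a significant infit
      # deviation in the same direction (one-sided standardised fit)
      side <- sign(inf$infit_msq[out] - 1)
      tc <- dc$infit$infit_t[match(inf$item[out], dc$infit$item)]
      crit <- stats::qnorm(1 - config$alpha_level)
      out <- out[sign(tc) == side & abs(tc) >= crit]
    }
    if (!length(out)) break
    worst <- out[which.max(abs(log(inf$infit_msq[out])))]
    need()
    elog <- rbind(elog, data.frame(
      stage = "misfit", item = inf$item[worst],
      reason = sprintf("infit mean square %.3f outside [%.2f, %.2f]",
                       inf$infit_msq[worst], config$infit_bounds[1],
                       config$infit_bounds[2]),
      statistic = inf$infit_msq[worst]))
    current <- drop_from(current, inf$item[worst])
    if (!is.null(confirm_cur))
      confirm_cur <- drop_from(confirm_cur, inf$item[worst])
  }
  d <- diagnose(current)
  list(log = elog, retained = colnames(current), fit = d$fit, infit = d$infit,
       q3 = d$q3)
}

#' @export
print.rasch_validation <- function(x, ...) {
  cat("Rasch scale validation\n")
  cat(sprintf("  calibration/validation: 2 x %d persons\n",
              x$config$n_per_sample))
  cat(sprintf("  dimensions retained (initial set): calibration %d, validation %d\n",
              x$diagnostics$calibration$pa_initial$n_retained,
              x$diagnostics$validation$pa_initial$n_retained))
  if (nrow(x$elimination_log)) {
    cat("  eliminated items:\n")
    for (i in seq_len(nrow(x$elimination_log)))
      cat(sprintf("    [%s] %s: %s\n", x$elimination_log$stage[i],
                  x$elimination_log$item[i], x$elimination_log$reason[i]))
  } else cat("  eliminated items: none\n")
  cat(sprintf("  retained (%d): %s\n", length(x$retained_items),
              paste(x$retained_items, collapse = ", ")))
  cat(sprintf("  dimensions retained (retained set): calibration %d, validation %d\n",
              x$diagnostics$calibration$pa_retained$n_retained,
              x$diagnostics$validation$pa_retained$n_retained))
  for (cv in names(x$dif)) {
    fl <- x$dif[[cv]]$calibration$table$item[x$dif[[cv]]$calibration$table$flagged]
    fv <- x$dif[[cv]]$validation$table$item[x$dif[[cv]]$validation$table$flagged]
    cat(sprintf("  DIF by %s: calibration {%s} tau2=%.3f (%s); validation {%s} tau2=%.3f (%s)\n",
                cv, paste(fl, collapse = ","),
                x$dif[[cv]]$calibration$tau2, x$dif[[cv]]$calibration$effect_band,
                paste(fv, collapse = ","),
                x$dif[[cv]]$validation$tau2, x$dif[[cv]]$validation$effect_band))
  }
  for (nm in names(x$reliability$calibration)) {
    rc <- x$reliability$calibration[[nm]]
    rv <- x$reliability$validation[[nm]]
    if (is.null(rc) || is.null(rv)) next
    cat(sprintf("  reliability [%s]: alpha %.2f/%.2f, PSI %.2f/%.2f (cal/val)\n",
                nm, rc$alpha, rv$alpha, rc$psi, rv$psi))
  }
  cat(sprintf("  validation agreement: %d/%d items\n",
              sum(x$agreement$agree), nrow(x$agreement)))
  invisible(x)
}

#' @export
summary.rasch_validation <- function(object, ...) {
  print(object, ...)
  cat("\nFinal calibration item difficulties:\n")
  print(summary(object$diagnostics$calibration$fit))
  invisible(object)
}

#' Serialise a validation result to a report list
#'
#' Flattens a [rasch_validate()] result into plain vectors and data frames
#' suitable for JSON serialisation (e.g. `jsonlite::write_json`).
#'
#' @param x a `rasch_validation` object.
#' @return A named list.
#' @export
validation_report <- function(x) {
  stopifnot(inherits(x, "rasch_validation"))
  pa_block <- function(pa) list(observed = pa$observed_eigenvalues,
                                adjusted = pa$adjusted_eigenvalues,
                                n_retained = pa$n_retained)
  rel_block <- function(r) if (is.null(r)) NULL else
    list(alpha = r$alpha, psi = r$psi, n_items = r$n_items,
         pass_alpha = r$pass_alpha, pass_psi = r$pass_psi)
  list(retained_items = x$retained_items,
       elimination_log = x$elimination_log,
       parallel_analysis = lapply(x$diagnostics, function(d)
         list(initial = pa_block(d$pa_initial),
              retained = pa_block(d$pa_retained))),
       item_difficulties = as.list(x$diagnostics$calibration$fit$beta),
       infit = as.data.frame(x$diagnostics$calibration$infit),
       dif = lapply(x$dif, function(d) lapply(d, function(s)
         c(list(table = s$table), s[c("tau2", "effect_band")]))),
       reliability = lapply(x$reliability, function(side)
         lapply(side, rel_block)),
       agreement = x$agreement,
       seed = x$config$seed)
}

#' Wright map of persons and items
#'
#' Draws the joint distribution of person measures (histogram) and item
#' difficulties (point markers) on one shared logit axis, the standard
#' person-item map of Rasch measurement. The plain-text rendering and the
#' graphic derive from the same numeric arrays stored in the validation
#' result.
#'
#' @param x a `rasch_validation` result or a [rasch_cml()] fit.
#' @param file optional path: when given, a PNG is written there.
#' @param ... passed to the plotting routine.
#' @return Invisibly, a character vector with the text rendering (one line
#'   per histogram bin / item).
#' @export
wright_map <- function(x, file = NULL, ...) {
  wd <- if (inherits(x, "rasch_validation")) {
    x$wright_map_data
  } else if (inherits(x, "rasch_cml")) {
    persons <- ability_wle(x)
    h <- graphics::hist(persons$theta, breaks = "Sturges", plot = FALSE)
    list(theta = persons$theta, beta = x$beta,
         hist_breaks = h$breaks, hist_counts = h$counts)
  } else stop_raschval("wright_map needs a rasch_validation or rasch_cml object")
  if (!length(wd$theta)) stop_raschval("no person measures to map")
  txt <- wright_text(wd)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_wright(wd$theta, wd$beta, wd = wd, ...)
  }
  invisible(txt)
}

# text rendering: one line per histogram bin, items placed in their bin
wright_text <- function(wd) {
  nb <- length(wd$hist_counts)
  lines <- character(nb)
  scale <- max(1, max(wd$hist_counts))
  for (b in seq_len(nb)) {
    lo <- wd$hist_breaks[b]; hi <- wd$hist_breaks[b + 1]
    items <- names(wd$beta)[wd$beta >= lo & (wd$beta < hi |
                              (b == nb & wd$beta == hi))]
    bar <- strrep("#", round(40 * wd$hist_counts[b] / scale))
    lines[b] <- sprintf("%6.2f..%6.2f |%-40s| %s", lo, hi, bar,
                        paste(items, collapse = ", "))
  }
  c("persons (#) and items along the latent trait (logits)", rev(lines))
}

plot_wright <- function(theta, beta, wd = NULL, main = "Wright map", ...) {
  if (is.null(wd)) {
    h <- graphics::hist(theta, breaks = "Sturges", plot = FALSE)
    wd <- list(hist_breaks = h$breaks, hist_counts = h$counts)
  }
  rng <- range(c(wd$hist_breaks, beta))
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NULL, xlim = rng, ylim = c(0, max(wd$hist_counts)),
                 xlab = "", ylab = "persons", main = main)
  graphics::rect(utils::head(wd$hist_breaks, -1), 0, wd$hist_breaks[-1],
                 wd$hist_counts, col = "grey80")
  graphics::par(mar = c(4, 4, 0, 1))
  graphics::plot(beta, rep(1, length(beta)), xlim = rng, yaxt = "n",
                 ylab = "items", xlab = "latent trait (logits)", pch = 17)
  graphics::text(beta, 1, labels = names(beta), srt = 90, adj = c(0, 0.5),
                 cex = 0.8)
  invisible(NULL)
}

#' @export
plot.rasch_validation <- function(x, ...) {
  plot_wright(x$wright_map_data$theta, x$wright_map_data$beta,
              wd = x$wright_map_data, ...)
}
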