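#' Load a scenario configuration file
#'
#' Reads a YAML scenario file in the package's documented dialect and
#' validates it strictly: unknown keys are errors naming the key (a silent
#' typo in a parameter name would invalidate scientific output).  The
#' dialect has four top-level blocks:
#'
#' * `label`: free-text scenario name.
#' * `parameters`: any of the fields of [macro_params()]; omitted fields
#'   take the package defaults.
#' * `run`: solver settings `t_end`, `method` (`"adaptive"`/`"euler"`),
#'   `dt`, `rtol`, `n_samples`; omitted settings take the defaults of
#'   [simulate_macro()].
#' * `panels` (optional): the two-nutrient-by-three-biocontrol scenario
#'   grid used by [panel_grid()]: `N0_high`, `N0_low`, `B_levels`.
#'
#' Which values were defaulted is retained (attribute `"defaulted"`) so
#' runs can log their full provenance.
#'
#' @param path path to a YAML scenario file.
#' @return An object of class `macro_scenario`: a list with `label`,
#'   `params` (a validated [macro_params()]), `run`, and `panels` (or
#'   `NULL`), with attribute `defaulted`.
#' @examples
#' cfg <- load_scenario(system.file("extdata", "baseline.yaml",
#'                                  package = "macroshift"))
#' cfg$params
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", sQuote(path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse scenario file ", sQuote(path), ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(raw)) stop("scenario file must be a YAML mapping",
                          call. = FALSE)
  known_top <- c("label", "parameters", "run", "panels")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0L) {
    stop("unknown key(s) in scenario file: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }

  par_block <- raw$parameters %||% list()
  unknown <- setdiff(names(par_block), macro_param_names())
  if (length(unknown) > 0L) {
    stop("unknown key(s) in 'parameters' block: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  params <- do.call(macro_params, par_block)

  run_defaults <- list(t_end = 200, method = "adaptive", dt = 0.01,
                       rtol = 1e-8, n_samples = 1000)
  run_block <- raw$run %||% list()
  unknown <- setdiff(names(run_block), names(run_defaults))
  if (length(unknown) > 0L) {
    stop("unknown key(s) in 'run' block: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  run <- utils::modifyList(run_defaults, run_block)
  if (!run$method %in% c("adaptive", "euler")) {
    stop("'run.method' must be \"adaptive\" or \"euler\" (got ",
         sQuote(run$method), ")", call. = FALSE)
  }
  for (nm in c("t_end", "dt", "rtol")) {
    if (!is.numeric(run[[nm]]) || length(run[[nm]]) != 1L ||
        run[[nm]] <= 0) {
      stop("'run.", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (run$n_samples < 2) stop("'run.n_samples' must be at least 2",
                              call. = FALSE)

  panels <- NULL
  if (!is.null(raw$panels)) {
    known_panels <- c("N0_high", "N0_low", "B_levels")
    unknown <- setdiff(names(raw$panels), known_panels)
    if (length(unknown) > 0L) {
      stop("unknown key(s) in 'panels' block: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    panels <- raw$panels
    if (is.null(panels$N0_high) || is.null(panels$N0_low) ||
        is.null(panels$B_levels)) {
      stop("'panels' block needs 'N0_high', 'N0_low' and 'B_levels'",
           call. = FALSE)
    }
    if (!(panels$N0_high > 0 && panels$N0_low > 0 &&
          panels$N0_low < panels$N0_high)) {
      stop("'panels' block needs 0 < N0_low < N0_high", call. = FALSE)
    }
    if (length(panels$B_levels) < 1L || any(panels$B_levels < 0)) {
      stop("'panels.B_levels' must be non-negative rates", call. = FALSE)
    }
  }

  defaulted <- c(
    setdiff(macro_param_names(), names(par_block)),
    paste0("run.", setdiff(names(run_defaults), names(run_block)))
  )
  structure(list(label = raw$label %||% "unnamed",
                 params = params, run = run, panels = panels),
            defaulted = defaulted, class = "macro_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration file
#'
#' Serialises a `macro_scenario` back to the YAML dialect of
#' [load_scenario()].  A written file re-loads to an identical scenario
#' (round-trip invariant).
#'
#' @param scenario a `macro_scenario`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "macro_scenario"))
  out <- list(label = scenario$label,
              parameters = unclass(scenario$params),
              run = scenario$run)
  if (!is.null(scenario$panels)) out$panels <- scenario$panels
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.macro_scenario <- function(x, ...) {
  cat(sprintf("<macro_scenario> %s\n", x$label))
  print(x$params)
  cat(sprintf("  run: t_end = %g, method = %s, dt = %g, rtol = %g, ",
              x$run$t_end, x$run$method, x$run$dt, x$run$rtol))
  cat(sprintf("n_samples = %d\n", as.integer(x$run$n_samples)))
  if (!is.null(x$panels)) {
    cat(sprintf("  panels: N0 high/low = %g/%g, B levels = %s\n",
                x$panels$N0_high, x$panels$N0_low,
                paste(x$panels$B_levels, collapse = ", ")))
  }
  d <- attr(x, "defaulted")
  if (length(d) > 0L) {
    cat("  defaulted:", paste(d, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the six-panel regime-shift scenario grid
#'
#' Simulates the model across the bundled scenario grid -- two nutrient
#' settings (high and low `N0`) crossed with three biocontrol rates
#' (none, intermediate, strong) -- and summarises each panel: final
#' biomasses, dominant species, switch time, and the steepest submerged
#' growth rate along the trajectory (`max dS/dt`, the "suddenness" of the
#' switch).  The qualitative ordering expectations are evaluated and
#' reported as pass/fail:
#'
#' 1. no biocontrol, high nutrients: floating dominance, no switch;
#' 2. intermediate biocontrol: still floating-dominant, but a sharper
#'    submerged rise than without control;
#' 3. strong biocontrol: a complete dominance switch at a finite time;
#' 4. the same progression at low nutrients;
#' 5. lower nutrients give reduced slopes (smaller `max dS/dt`) at every
#'    matched biocontrol level;
#' 6. the complete switch requires less biocontrol at low nutrients
#'    (exclusion threshold comparison; see [critical_biocontrol()]).
#'
#' @param scenario a `macro_scenario` with a `panels` block, or `NULL`
#'   for the bundled baseline scenario.
#' @param thresholds logical; also compute the critical biocontrol
#'   thresholds at both nutrient settings (needed for check 6).
#' @return An object of class `macro_panels`: a list with `trajectories`
#'   (named list of `macro_traj`), `summary` (one row per panel),
#'   `checks` (data frame of the six expectations with pass/fail), and
#'   `thresholds`.
#' @examples
#' \donttest{
#' pg <- panel_grid()
#' pg$summary
#' pg$checks
#' }
#' @export
panel_grid <- function(scenario = NULL, thresholds = TRUE) {
  if (is.null(scenario)) {
    scenario <- load_scenario(system.file("extdata", "baseline.yaml",
                                          package = "macroshift"))
  }
  stopifnot(inherits(scenario, "macro_scenario"))
  if (is.null(scenario$panels)) {
    stop("scenario has no 'panels' block", call. = FALSE)
  }
  pn <- scenario$panels
  run <- scenario$run
  settings <- expand.grid(B = pn$B_levels,
                          N0 = c(pn$N0_high, pn$N0_low))
  settings$nutrients <- rep(c("high", "low"), each = length(pn$B_levels))
  trajectories <- list()
  rows <- list()
  for (i in seq_len(nrow(settings))) {
    p <- scenario$params
    p$N0 <- settings$N0[i]
    p$B <- settings$B[i]
    label <- sprintf("%sN_B%g", settings$nutrients[i], settings$B[i])
    traj <- simulate_macro(p, t_end = run$t_end, method = run$method,
                           dt = run$dt, rtol = run$rtol,
                           n_samples = run$n_samples)
    r <- macro_rhs(traj$F, traj$S, attr(traj, "params"))
    sw <- detect_switch(traj)
    n <- nrow(traj)
    trajectories[[label]] <- traj
    rows[[label]] <- data.frame(
      panel = label, nutrients = settings$nutrients[i],
      N0 = settings$N0[i], B = settings$B[i],
      F_end = traj$F[n], S_end = traj$S[n], N_end = traj$N[n],
      dominant = if (traj$F[n] > traj$S[n]) "floating"
                 else if (traj$S[n] > traj$F[n]) "submerged" else "tie",
      t_switch = sw$t_switch, switch_status = sw$status,
      max_dSdt = max(r$dS),
      floating_extinct = unname(attr(traj, "extinct")["F"]))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  thr <- NULL
  if (isTRUE(thresholds)) {
    p_hi <- scenario$params; p_hi$N0 <- pn$N0_high
    p_lo <- scenario$params; p_lo$N0 <- pn$N0_low
    thr <- list(high = critical_biocontrol(p_hi),
                low = critical_biocontrol(p_lo))
  }

  hi <- summary[summary$nutrients == "high", ]
  lo <- summary[summary$nutrients == "low", ]
  nb <- length(pn$B_levels)
  checks <- data.frame(
    check = c(
      "high nutrients, no control: floating dominance, no switch",
      "high nutrients, mid control: floating dominance, sharper S rise",
      "high nutrients, strong control: complete switch, finite time",
      "low nutrients: same three-level progression",
      "low nutrients: reduced slopes (smaller max dS/dt) at matched B",
      "complete switch needs less control at low nutrients"
    ),
    pass = c(
      hi$dominant[1L] == "floating" && hi$switch_status[1L] != "switch",
      nb >= 2L && hi$dominant[2L] == "floating" &&
        hi$max_dSdt[2L] > hi$max_dSdt[1L],
      nb >= 3L && hi$dominant[3L] == "submerged" &&
        hi$switch_status[3L] == "switch" && is.finite(hi$t_switch[3L]),
      nb >= 3L && lo$dominant[1L] == "floating" &&
        lo$switch_status[1L] != "switch" && lo$dominant[2L] == "floating" &&
        lo$max_dSdt[2L] > lo$max_dSdt[1L] &&
        lo$dominant[3L] == "submerged" && lo$switch_status[3L] == "switch",
      all(lo$max_dSdt < hi$max_dSdt),
      if (is.null(thr)) NA else
        isTRUE(thr$low$exclusion < thr$high$exclusion)
    )
  )
  structure(list(trajectories = trajectories, summary = summary,
                 checks = checks, thresholds = thr,
                 scenario = scenario),
            class = "macro_panels")
}

#' @export
print.macro_panels <- function(x, ...) {
  cat("<macro_panels> six-panel regime-shift grid\n")
  print(x$summary, row.names = FALSE, digits = 5)
  cat("\nqualitative checks:\n")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s\n",
                if (isTRUE(x$checks$pass[i])) "pass"
                else if (is.na(x$checks$pass[i])) " -- " else "FAIL",
                x$checks$check[i]))
  }
  if (!is.null(x$thresholds)) {
    cat(sprintf(paste0("\nexclusion threshold: %.4f (high N0), ",
                       "%.4f (low N0); dominance flip: %.4f / %.4f\n"),
                x$thresholds$high$exclusion, x$thresholds$low$exclusion,
                x$thresholds$high$dominance, x$thresholds$low$dominance))
  }
  invisible(x)
}

#' Plot the six-panel scenario grid
#'
#' One panel per scenario in a 2x3 layout (rows: high/low nutrients;
#' columns: increasing biocontrol), each drawn with [plot.macro_traj()].
#'
#' @param x a `macro_panels`.
#' @param ... passed to [plot.macro_traj()].
#' @return Invisibly, `x`.
#' @export
plot.macro_panels <- function(x, ...) {
  nb <- length(x$scenario$panels$B_levels)
  old <- graphics::par(mfrow = c(2L, nb), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$trajectories)) {
    plot(x$trajectories[[nm]], main = nm, ...)
  }
  invisible(x)
}
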