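#' Assemble a run configuration
#'
#' Bundles every knob a pipeline run needs: model constants, the emulsion,
#' the a3/a4 arrest multiplier, the concentration grid and the seed. All
#' values pass through the type constructors, so invariant violations fail
#' here, naming the offending key.
#'
#' @param phi_c,phi_star,eta_ratio_criterion,w_threshold,wtpct_to_kgm3,avogadro
#'   See [model_constants()].
#' @param sauter_diameter_um,oil_fraction See [emulsion_spec()].
#' @param arrest_multiplier See [classify_regime()].
#' @param c_grid Concentration grid in wt%.
#' @param seed Integer seed for the synthetic generators.
#' @param out_dir Output directory for report files.
#' @return A list of class `run_config` with elements `constants`, `emulsion`,
#'   `arrest_multiplier`, `c_grid`, `seed`, `out_dir`.
#' @export
run_config <- function(phi_c = 0.57, phi_star = 0.53, eta_ratio_criterion = 100,
                       w_threshold = 4, wtpct_to_kgm3 = 10, avogadro = 6.022e23,
                       sauter_diameter_um = 2.0, oil_fraction = 0.064,
                       arrest_multiplier = 2,
                       c_grid = c(0.025, 0.05, 0.1, 0.25, 0.5, 1.0),
                       seed = 1L, out_dir = ".") {
  constants <- model_constants(phi_c, phi_star, eta_ratio_criterion,
                               w_threshold, wtpct_to_kgm3, avogadro)
  emulsion <- emulsion_spec(sauter_diameter_um, oil_fraction)
  stop_unless(is_scalar_num(arrest_multiplier) && arrest_multiplier >= 1,
              "arrest_multiplier must be >= 1")
  stop_unless(is.numeric(c_grid) && all(c_grid >= 0) &&
                !is.unsorted(c_grid, strictly = TRUE),
              "c_grid must be strictly increasing non-negative concentrations")
  stop_unless(is_scalar_num(seed) && seed == round(seed), "seed must be an integer")
  structure(list(constants = constants, emulsion = emulsion,
                 arrest_multiplier = arrest_multiplier, c_grid = c_grid,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a flat key-value file
#'
#' Accepts lines of the form `key = value` (`#` comments and blank lines
#' ignored). Absent keys take the package defaults; every effective value is
#' echoed to the log. `c_grid` takes a comma-separated list.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param quiet Suppress the configuration echo.
#' @return A `run_config`.
#' @examples
#' cfg <- load_config(NULL, quiet = TRUE)   # all defaults
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  overrides <- list()
  if (!is.null(path)) {
    stop_unless(is.character(path) && length(path) == 1L && file.exists(path),
                "config file not found")
    for (ln in readLines(path, warn = FALSE, encoding = "UTF-8")) {
      ln <- sub("#.*$", "", ln)
      if (!nzchar(trimws(ln))) next
      if (!grepl("=", ln, fixed = TRUE))
        stop(sprintf("malformed config line (expected key = value): '%s'", ln),
             call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      known <- names(formals(run_config))
      if (!key %in% known)
        stop(sprintf("unknown config key '%s' (known: %s)", key,
                     paste(known, collapse = ", ")), call. = FALSE)
      parsed <- if (key == "out_dir") val else {
        num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
        if (anyNA(num))
          stop(sprintf("config key '%s' has non-numeric value '%s'", key, val),
               call. = FALSE)
        num
      }
      overrides[[key]] <- parsed
    }
  }
  cfg <- tryCatch(do.call(run_config, overrides), error = function(e)
    stop(sprintf("invalid configuration: %s", conditionMessage(e)), call. = FALSE))
  if (!quiet) {
    message("effective configuration:")
    cs <- cfg$constants
    for (k in names(cs)) message(sprintf("  %s = %g", k, cs[[k]]))
    message(sprintf("  sauter_diameter_um = %g", cfg$emulsion$sauter_diameter))
    message(sprintf("  oil_fraction = %g", cfg$emulsion$oil_fraction))
    message(sprintf("  arrest_multiplier = %g", cfg$arrest_multiplier))
    message(sprintf("  c_grid = %s", paste(cfg$c_grid, collapse = ", ")))
    message(sprintf("  seed = %d", cfg$seed))
  }
  cfg
}

#' Command-line dispatcher
#'
#' Thin shell entry point over the package functions, for scripted use via
#' `Rscript`. Subcommands: `cvc`, `cfc`, `classify`, `phase-diagram`,
#' `fit-scaling`, `synth`, `report`. Common options: `--polymers <csv>`,
#' `--config <file>`, `--out <tsv>` (default stdout), `--quiet`;
#' `synth` takes `--what polymers|droplets`, `--n`, `--seed`;
#' `report` takes `--out-dir` and writes the full report set.
#'
#' @param argv Character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status: 0 success, 1 computation error, 2 usage error.
#' @examples
#' cli_dispatch(c("cvc", "--quiet"))
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: deplstab <subcommand> [options]",
    "subcommands:",
    "  cvc            critical viscosity concentrations of a polymer table",
    "  cfc            critical flocculation concentrations of a polymer table",
    "  classify       regime classification over the configured grid",
    "  phase-diagram  full polymer x concentration stability table",
    "  fit-scaling    Rh-Mw power-law fit of a polymer table",
    "  synth          generate synthetic polymers or droplets",
    "  report         write the reproduction, phase-diagram and extract reports",
    "options: --polymers <csv> --config <file> --out <tsv> --json <file>",
    "         --out-dir <dir> --what polymers|droplets --n <int> --seed <int>",
    "         --conc <wt%,wt%,...> --quiet",
    sep = "\n")
  if (length(argv) == 0L || argv[1] %in% c("-h", "--help", "help")) {
    message(usage)
    return(if (length(argv) == 0L) 2L else 0L)
  }
  subcmd <- argv[1]
  known <- c("cvc", "cfc", "classify", "phase-diagram", "fit-scaling",
             "synth", "report")
  if (!subcmd %in% known) {
    message(sprintf("unknown subcommand '%s'\n%s", subcmd, usage))
    return(2L)
  }
  opts <- tryCatch(parse_cli_options(argv[-1]), error = function(e) {
    message(sprintf("argument error: %s\n%s", conditionMessage(e), usage))
    NULL
  })
  if (is.null(opts)) return(2L)
  quiet <- isTRUE(opts$quiet)
  status <- tryCatch({
    cfg <- load_config(opts$config, quiet = quiet)
    run_subcommand(subcmd, opts, cfg, quiet)
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    1L
  })
  status
}

parse_cli_options <- function(args) {
  flags <- c("--quiet")
  valued <- c("--polymers", "--config", "--out", "--json", "--out-dir",
              "--what", "--n", "--seed", "--conc")
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% flags) {
      opts[[sub("^--", "", a)]] <- TRUE
      i <- i + 1L
    } else if (a %in% valued) {
      if (i == length(args)) stop(sprintf("option %s needs a value", a))
      key <- gsub("-", "_", sub("^--", "", a))
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop(sprintf("unrecognised argument '%s'", a))
    }
  }
  opts
}

run_subcommand <- function(subcmd, opts, cfg, quiet) {
  out <- if (is.null(opts$out)) "" else opts$out
  polymers <- if (is.null(opts$polymers)) reference_polymer_table() else
    read_polymer_table(opts$polymers)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  ps <- as_polymer_list(polymers)
  if (subcmd == "cvc") {
    df <- data.frame(
      name = vapply(ps, `[[`, character(1), "name"),
      mw_kg_per_mol = vapply(ps, `[[`, numeric(1), "mw"),
      rh_nm = vapply(ps, `[[`, numeric(1), "rh"),
      cvc_wtpct = vapply(ps, cvc, numeric(1), constants = cfg$constants))
    df$cvc_table = truncate_decimals(df$cvc_wtpct, 2)
    write_report_tsv(df, out, opts$json)
  } else if (subcmd == "cfc") {
    rows <- lapply(ps, function(p) {
      r <- cfc(p, cfg$emulsion, cfg$constants)
      data.frame(name = p$name, mw_kg_per_mol = p$mw, rh_nm = p$rh,
                 cfc_wtpct = r$cfc, cfc_table = truncate_decimals(r$cfc, 3),
                 w_contact_kt = r$w_contact, quad_a = r$quad_a, quad_b = r$quad_b)
    })
    write_report_tsv(do.call(rbind, rows), out, opts$json)
  } else if (subcmd %in% c("classify", "phase-diagram")) {
    grid <- if (!is.null(opts$conc)) {
      g <- suppressWarnings(as.numeric(strsplit(opts$conc, ",")[[1]]))
      if (anyNA(g)) stop("--conc must be a comma-separated numeric list")
      g
    } else cfg$c_grid
    df <- phase_diagram(ps, cfg$emulsion, grid, cfg$constants,
                        cfg$arrest_multiplier)
    write_report_tsv(df, out, opts$json)
  } else if (subcmd == "fit-scaling") {
    f <- fit_rh_scaling(ps)
    write_report_tsv(
      data.frame(k = f$k, nu = f$nu, residual_se = f$residual_se,
                 se_log_k = f$se_log_k, se_nu = f$se_nu, n = f$n),
      out, opts$json)
  } else if (subcmd == "synth") {
    what <- if (is.null(opts$what)) "polymers" else opts$what
    n <- if (is.null(opts$n)) 10L else as.integer(opts$n)
    seed <- if (is.null(opts$seed)) cfg$seed else as.integer(opts$seed)
    if (what == "polymers") {
      fam <- generate_polymer_family(n, fit_rh_scaling(ps), seed = seed)
      if (nzchar(out)) write_polymer_table(fam, out) else
        print(utils::head(do.call(rbind, lapply(fam, as.data.frame)), n))
      log_msg("wrote %d synthetic polymers (seed %d)", n, seed)
    } else if (what == "droplets") {
      pop <- generate_droplet_population(n, seed = seed)
      df <- data.frame(diameter_um = pop$diameters)
      write_report_tsv(df, out)
      log_msg("wrote %d droplet diameters, sample d32 = %.4g um (seed %d)",
              n, sauter_diameter(pop), seed)
    } else stop("--what must be 'polymers' or 'droplets'")
  } else if (subcmd == "report") {
    dir <- if (is.null(opts$out_dir)) cfg$out_dir else opts$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_report_tsv(reproduction_report(polymers, emulsion = cfg$emulsion,
                                         constants = cfg$constants),
                     file.path(dir, "reproduction_report.tsv"),
                     file.path(dir, "reproduction_report.json"))
    write_report_tsv(phase_diagram(ps, cfg$emulsion, cfg$c_grid, cfg$constants,
                                   cfg$arrest_multiplier),
                     file.path(dir, "phase_diagram.tsv"))
    write_report_tsv(extract_stability_report(emulsion = cfg$emulsion,
                                              constants = cfg$constants,
                                              arrest_multiplier = cfg$arrest_multiplier),
                     file.path(dir, "extract_stability.tsv"))
    f <- fit_rh_scaling(ps)
    write_report_tsv(
      data.frame(k = f$k, nu = f$nu, residual_se = f$residual_se,
                 se_log_k = f$se_log_k, se_nu = f$se_nu, n = f$n),
      file.path(dir, "scaling_fit.tsv"))
    log_msg("wrote reports to %s", dir)
  }
  invisible(NULL)
}
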