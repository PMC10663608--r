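VESICLE_COLUMNS <- c("vesicle_id", "experiment_id", "receptor_variant",
                     "ligand", "ligand_conc_nM", "py_site",
                     "receptor_fluor", "antibody_fluor", "ligand_fluor")
VESICLE_REQUIRED <- setdiff(VESICLE_COLUMNS, "ligand_fluor")

#' Read a single-vesicle table
#'
#' Reads the delimited vesicle-table format: a header row with columns
#' `vesicle_id, experiment_id, receptor_variant, ligand, ligand_conc_nM,
#' py_site, receptor_fluor, antibody_fluor, ligand_fluor` (the last
#' optional/empty), comma- or tab-separated, '.' decimal separator.
#' Malformed rows (unparseable numbers, nonpositive receptor fluorescence,
#' negative concentration) are reported with their file line numbers; in
#' strict mode any malformed row is an error, otherwise such rows are
#' dropped.
#'
#' @param path file path.
#' @param format `"auto"` (by extension, default), `"csv"` or `"tsv"`.
#' @param strict fail on any malformed row (default `FALSE`).
#' @return `data.frame` of typed records; the validation report (a
#'   `data.frame` of `line`, `problem`) is in attribute
#'   `"validation_report"`.
#' @export
read_vesicle_table <- function(path, format = c("auto", "csv", "tsv"),
                               strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""),
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(VESICLE_REQUIRED, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"ligand_fluor" %in% names(raw)) raw$ligand_fluor <- NA_character_

  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1
  problems <- list()
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  conc <- num("ligand_conc_nM")
  rec <- num("receptor_fluor")
  ab <- num("antibody_fluor")
  lig <- num("ligand_fluor")

  flag <- function(idx, why) {
    if (any(idx)) problems[[length(problems) + 1L]] <<-
        data.frame(line = lines[idx], problem = why)
    idx
  }
  bad <- flag(is.na(conc) & !is.na(raw$ligand_conc_nM) |
                is.na(raw$ligand_conc_nM), "unparseable ligand_conc_nM")
  bad <- bad | flag(!is.na(conc) & conc < 0, "negative ligand_conc_nM")
  bad <- bad | flag(is.na(rec), "unparseable receptor_fluor")
  bad <- bad | flag(!is.na(rec) & rec <= 0, "nonpositive receptor_fluor")
  bad <- bad | flag(is.na(ab), "unparseable antibody_fluor")
  bad <- bad | flag(!is.na(ab) & ab < 0, "negative antibody_fluor")
  bad <- bad | flag(!is.na(raw$ligand_fluor) & is.na(lig), "unparseable ligand_fluor")

  report <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(0), problem = character(0))
  if (strict && nrow(report)) {
    stop(sprintf("malformed row(s) at line(s) %s: %s",
                 paste(unique(report$line), collapse = ", "),
                 paste(unique(report$problem), collapse = "; ")), call. = FALSE)
  }

  out <- data.frame(
    vesicle_id = raw$vesicle_id,
    experiment_id = raw$experiment_id,
    receptor_variant = raw$receptor_variant,
    ligand = raw$ligand,
    ligand_conc_nM = conc,
    py_site = raw$py_site,
    receptor_fluor = rec,
    antibody_fluor = ab,
    ligand_fluor = lig,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation_report") <- report
  out
}

#' Write a single-vesicle table
#'
#' @param records vesicle-record `data.frame`.
#' @param path output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_vesicle_table <- function(records, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  cols <- intersect(VESICLE_COLUMNS, names(records))
  out <- records[, cols, drop = FALSE]
  # full-precision round trip for the numeric channels
  for (cc in c("ligand_conc_nM", "receptor_fluor", "antibody_fluor", "ligand_fluor")) {
    if (cc %in% names(out)) {
      v <- out[[cc]]
      out[[cc]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Configuration is JSON (or YAML when the `yaml` package is installed).
#' Unknown top-level keys are rejected. See [run_pipeline()] for the
#' recognised fields.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_run_config(cfg)
}

#' Build a run configuration in code
#'
#' @param ... configuration fields; see [run_pipeline()].
#' @return validated `run_config` list.
#' @export
run_config <- function(...) as_run_config(list(...))

as_run_config <- function(cfg) {
  allowed <- c("seed", "output_dir", "e0_mode", "fit_target", "mc", "bin",
               "inputs", "simulate", "response_A", "response_B",
               "reference_ligand", "reference_variant", "format", "strict")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- list(seed = 1L, output_dir = NULL, e0_mode = "subtract",
                   fit_target = "vesicles",
                   mc = list(n_draws = 1e6, seed = NULL),
                   bin = list(width = 0.1, min_n = 50),
                   inputs = NULL, simulate = NULL,
                   response_A = "Y1068", response_B = "Y1173",
                   reference_ligand = "EGF", reference_variant = "WT",
                   format = "csv", strict = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$e0_mode <- match.arg(cfg$e0_mode, c("subtract", "free", "none"))
  cfg$fit_target <- match.arg(cfg$fit_target, c("vesicles", "means"))
  cfg$format <- match.arg(cfg$format, c("csv", "tsv"))
  if (is.null(cfg$mc$n_draws)) cfg$mc$n_draws <- 1e6
  if (is.null(cfg$bin$width)) cfg$bin$width <- 0.1
  if (is.null(cfg$bin$min_n)) cfg$bin$min_n <- 50
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    stop("config must provide 'inputs' (paths) or 'simulate' (generator specs)",
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_checksum <- function(cfg) {
  cfg <- unclass(cfg)
  # identify the analysis, not the output location
  cfg[c("output_dir", "format")] <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

hill_fit_record <- function(fit) {
  list(E_top = fit$E_top, E_top_se = fit$E_top_se,
       EC50 = fit$EC50, EC50_se = fit$EC50_se,
       E0 = fit$E0, E0_se = fit$E0_se,
       hill_slope = fit$hill_slope,
       cov_Etop_EC50 = fit$cov["top", "half"],
       n_points = fit$n_points, converged = fit$converged,
       ec50_identifiable = fit$ec50_identifiable,
       e0_mode = fit$e0_mode)
}

bias_record <- function(co) {
  list(value = co$value, se = co$se, kind = co$kind,
       response_A = co$response_A, response_B = co$response_B,
       test_entity = co$test_entity, reference_entity = co$reference_entity,
       sign_convention = "positive = response_A preferred",
       beta_star_rule = "beta_star_test = beta_rel + beta_star_ref",
       mc = co$mc)
}

#' Run the full bias-quantification pipeline
#'
#' Orchestrates the analysis end to end. Vesicle records are loaded from
#' `inputs` (paths) and/or generated by `simulate` specs; then for each
#' (receptor variant, ligand, phosphosite) group a constitutive-corrected
#' Hill fit is computed; bias plots and relative bias coefficients are
#' built for every ligand against the reference ligand (per variant) and
#' for the mutant against the wild-type (per ligand); for three-channel
#' groups the transducer function is fitted per phosphosite and the
#' absolute-bias chain is evaluated. Results, provenance (config checksum,
#' seed, package version) and decision flags are written to `output_dir`
#' when set.
#'
#' Recognised config fields: `seed`, `output_dir`, `e0_mode`
#' (`"subtract"`/`"free"`/`"none"`), `fit_target`
#' (`"vesicles"`/`"means"`), `mc` (`n_draws`, `seed`), `bin` (`width`,
#' `min_n`), `inputs` (character paths), `simulate` (list of generator
#' specs: [generative_config()] fields plus `receptor_variant`, `ligand`,
#' `py_site`, `three_channel`), `response_A`, `response_B`,
#' `reference_ligand`, `reference_variant`, `format`, `strict`.
#'
#' @param config a `run_config` (see [run_config()], [read_run_config()]).
#' @param records optional pre-loaded vesicle records, bypassing
#'   `inputs`/`simulate`.
#' @return result bundle (list) with `records` summary, `hill_fits`,
#'   `bias_plots`, `bias_coefficients`, `transducer`, `provenance`.
#' @export
run_pipeline <- function(config, records = NULL) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  mc <- mc_settings(n_draws = config$mc$n_draws,
                    seed = if (is.null(config$mc$seed)) config$seed else config$mc$seed)
  log_msg <- function(...) message(sprintf(...))

  if (is.null(records)) {
    records <- collect_records(config)
  }
  if (!nrow(records)) stop("no vesicle records to analyse", call. = FALSE)

  key <- interaction(records$receptor_variant, records$ligand, records$py_site,
                     drop = TRUE, sep = "|")
  groups <- split(records, key)
  log_msg("pipeline: %d records in %d condition groups", nrow(records), length(groups))

  hill_fits <- list()
  summaries <- list()
  for (g in names(groups)) {
    gr <- groups[[g]]
    summaries[[g]] <- aggregate_dose_response(gr)
    hill_fits[[g]] <- tryCatch(
      fit_hill(gr, e0_mode = config$e0_mode, target = config$fit_target),
      error = function(e) {
        log_msg("hill fit skipped for %s: %s", g, conditionMessage(e))
        NULL
      })
  }

  gkey <- function(v, l, s) paste(v, l, s, sep = "|")
  variants <- unique(records$receptor_variant)
  ligands <- unique(records$ligand)
  ref_lig <- config$reference_ligand
  ref_var <- config$reference_variant
  A <- config$response_A
  B <- config$response_B

  bias_plots <- list()
  coefficients <- list()

  for (v in variants) {
    for (l in ligands) {
      sAl <- summaries[[gkey(v, l, A)]]; sBl <- summaries[[gkey(v, l, B)]]
      if (!is.null(sAl) && !is.null(sBl)) {
        bias_plots[[sprintf("%s|%s", v, l)]] <-
          tryCatch(bias_plot(sAl, sBl), error = function(e) NULL)
      }
      if (l == ref_lig) next
      fAl <- hill_fits[[gkey(v, l, A)]]; fBl <- hill_fits[[gkey(v, l, B)]]
      fAr <- hill_fits[[gkey(v, ref_lig, A)]]; fBr <- hill_fits[[gkey(v, ref_lig, B)]]
      if (!is.null(fAl) && !is.null(fBl) && !is.null(fAr) && !is.null(fBr)) {
        coefficients[[sprintf("beta_lig|%s|%s_vs_%s", v, l, ref_lig)]] <-
          beta_lig(fAl, fBl, fAr, fBr, ligand = l, reference = ref_lig,
                   response_A = A, response_B = B, settings = mc)
      }
    }
  }
  if (length(setdiff(variants, ref_var))) {
    for (v in setdiff(variants, ref_var)) {
      for (l in ligands) {
        fAm <- hill_fits[[gkey(v, l, A)]]; fBm <- hill_fits[[gkey(v, l, B)]]
        fAw <- hill_fits[[gkey(ref_var, l, A)]]; fBw <- hill_fits[[gkey(ref_var, l, B)]]
        if (!is.null(fAm) && !is.null(fBm) && !is.null(fAw) && !is.null(fBw)) {
          coefficients[[sprintf("beta_mut|%s|%s_vs_%s", l, v, ref_var)]] <-
            beta_mut(fAm, fBm, fAw, fBw, mutant = v, reference = ref_var,
                     response_A = A, response_B = B, settings = mc)
        }
      }
    }
  }

  # transducer analysis on three-channel groups (per variant x ligand)
  transducer <- list()
  three <- records[!is.na(records$ligand_fluor), , drop = FALSE]
  if (nrow(three)) {
    tkey <- interaction(three$receptor_variant, three$ligand, drop = TRUE, sep = "|")
    for (g in levels(tkey)) {
      gr <- three[tkey == g, , drop = FALSE]
      sites <- intersect(c(A, B), unique(gr$py_site))
      fits <- list()
      for (s in sites) {
        gs <- gr[gr$py_site == s, , drop = FALSE]
        res <- tryCatch({
          fb <- scale_bound_fraction(gs)
          e0 <- estimate_constitutive(gs)
          resp <- compute_ratios(gs) - e0$E0
          tf <- fit_transducer(fb, resp)
          list(fit = tf,
               efficiency = phospho_efficiency(tf$K_resp, tf$K_resp_se, mc),
               binned = bin_transducer(fb, resp, config$bin$width, config$bin$min_n))
        }, error = function(e) {
          log_msg("transducer skipped for %s/%s: %s", g, s, conditionMessage(e))
          NULL
        })
        if (!is.null(res)) fits[[s]] <- res
      }
      if (length(fits) == 2) {
        lig_name <- strsplit(g, "|", fixed = TRUE)[[1]][2]
        bstar <- beta_star_from_kresp(
          fits[[A]]$fit$K_resp, fits[[B]]$fit$K_resp,
          fits[[A]]$fit$K_resp_se, fits[[B]]$fit$K_resp_se,
          ligand = lig_name, response_A = A, response_B = B, settings = mc)
        coefficients[[sprintf("beta_star|%s", g)]] <- bstar
        # chain relative coefficients against this ligand onto the absolute scale
        for (nm in names(coefficients)) {
          co <- coefficients[[nm]]
          if (co$kind != "absolute" && identical(co$reference_entity, lig_name)) {
            coefficients[[sprintf("beta_star|%s|%s", g, co$test_entity)]] <-
              beta_star_transfer(co, bstar, settings = mc)
          }
        }
      }
      if (length(fits)) transducer[[g]] <- fits
    }
  }

  provenance <- list(
    package = "vesiclebias",
    version = as.character(utils::packageVersion("vesiclebias")),
    seed = config$seed,
    config_md5 = config_checksum(config),
    e0_mode = config$e0_mode,
    fit_target = config$fit_target,
    beta_star_rule = "beta_star_test = beta_rel + beta_star_ref",
    timestamp = NULL  # kept NULL so reruns are byte-identical
  )

  bundle <- list(records_n = nrow(records),
                 summaries = summaries,
                 hill_fits = hill_fits,
                 bias_plots = bias_plots,
                 bias_coefficients = coefficients,
                 transducer = transducer,
                 provenance = provenance)

  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config)
  }
  invisible(bundle)
}

collect_records <- function(config) {
  parts <- list()
  if (!is.null(config$inputs)) {
    paths <- if (is.data.frame(config$inputs)) config$inputs$path else unlist(config$inputs)
    for (p in paths) {
      parts[[length(parts) + 1L]] <- read_vesicle_table(p, strict = isTRUE(config$strict))
    }
  }
  if (!is.null(config$simulate)) {
    sims <- config$simulate
    if (is.data.frame(sims)) {
      sims <- unname(split(sims, seq_len(nrow(sims))))
    } else if (!is.null(names(sims)) || (length(sims) && !is.list(sims[[1]]))) {
      sims <- list(sims)  # a single spec given directly
    }
    for (i in seq_along(sims)) {
      sp <- as.list(sims[[i]])
      # unwrap JSON/data.frame list-columns (e.g. ligand_concentrations)
      sp <- lapply(sp, function(v) if (is.list(v)) v[[1]] else v)
      labels <- list(
        receptor_variant = sp$receptor_variant %||% "WT",
        ligand = sp$ligand %||% "EGF",
        py_site = sp$py_site %||% "Y1068",
        experiment_id = sp$experiment_id %||% sprintf("sim%02d", i)
      )
      three <- isTRUE(sp$three_channel)
      sp[c("receptor_variant", "ligand", "py_site", "experiment_id",
           "three_channel")] <- NULL
      if (is.null(sp$seed)) sp$seed <- config$seed + i
      gc <- do.call(generative_config, sp)
      parts[[length(parts) + 1L]] <- if (three) {
        simulate_three_channel(gc, labels$receptor_variant, labels$ligand,
                               labels$py_site, labels$experiment_id)
      } else {
        simulate_dose_response(gc, labels$receptor_variant, labels$ligand,
                               labels$py_site, labels$experiment_id)
      }
    }
  }
  do.call(rbind, parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  sep <- if (config$format == "tsv") "\t" else ","
  ext <- config$format

  jsonlite::write_json(
    lapply(Filter(Negate(is.null), bundle$hill_fits), hill_fit_record),
    out("hill_fits.json"), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  jsonlite::write_json(
    lapply(bundle$bias_coefficients, bias_record),
    out("bias_coefficients.json"), auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)
  for (nm in names(bundle$summaries)) {
    fn <- out(sprintf("summary_%s.%s", gsub("[^A-Za-z0-9_.-]", "_", nm), ext))
    utils::write.table(bundle$summaries[[nm]], fn, sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  for (nm in names(bundle$bias_plots)) {
    if (is.null(bundle$bias_plots[[nm]])) next
    fn <- out(sprintf("biasplot_%s.%s", gsub("[^A-Za-z0-9_.-]", "_", nm), ext))
    utils::write.table(bundle$bias_plots[[nm]], fn, sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  if (length(bundle$transducer)) {
    trec <- lapply(bundle$transducer, function(fits) {
      lapply(fits, function(x) {
        f <- x$fit
        list(K_resp = f$K_resp, K_resp_se = f$K_resp_se,
             R_max = f$R_max, R_max_se = f$R_max_se,
             efficiency = x$efficiency$value, efficiency_se = x$efficiency$se,
             n_vesicles = f$n_vesicles, converged = f$converged)
      })
    })
    jsonlite::write_json(trec, out("transducer_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (g in names(bundle$transducer)) {
      for (s in names(bundle$transducer[[g]])) {
        fn <- out(sprintf("binned_%s_%s.%s",
                          gsub("[^A-Za-z0-9_.-]", "_", g), s, ext))
        utils::write.table(bundle$transducer[[g]][[s]]$binned, fn, sep = sep,
                           row.names = FALSE, quote = FALSE)
      }
    }
  }
  jsonlite::write_json(bundle$provenance, out("provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(config$output_dir)
}
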