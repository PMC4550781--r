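#' Configure an end-to-end analysis run
#'
#' Collects every tunable of the pipeline in one validated object. Input
#' can be a peak-table CSV, a pre-scored matrix TSV, or (default) the
#' canonical synthetic scenario; the expression arm runs from a Ct CSV,
#' the canonical synthetic Ct scenario, or is skipped.
#'
#' @param msap_input Path to an MSAP input file, or `NULL` to simulate
#'   the canonical scenario.
#' @param msap_format `"peaks"` or `"matrix"` (ignored when simulating).
#' @param ploidy_map Optional `sample`/`ploidy` data frame (or path to a
#'   two-column CSV) for file inputs; simulated input carries its own.
#' @param ct_input Path to a Ct CSV with columns
#'   `species,ploidy,gene,role,bio_rep,tech_rep,run_id,ct`; `"simulate"`
#'   for the canonical scenario; `NULL` to skip the expression arm.
#' @param flow_input Path to a flow-cytometry CSV with columns
#'   `species,replicate,peak_mean,cv`; `"simulate"`; or `NULL` to skip.
#' @param height_threshold Peak binarization threshold (default 50 RFU).
#' @param size_range Closed scoring window in bp (default `c(120, 480)`).
#' @param critical_value U significance threshold (default 1.96).
#' @param midvalue `"mean"` or `"median"` group mid-value.
#' @param n_sites,sim_mode Simulated fragments per sample and allocation
#'   mode (see [msap_scenario()]).
#' @param calibrator_species,irc_gene,irc_ploidies,efficiency Expression
#'   arm settings (see [chained_normalization()]).
#' @param reference_species Flow-cytometry reference species.
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory for the report bundle.
#' @return A `pipeline_config` object (a validated list).
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(msap_input = NULL, msap_format = c("peaks", "matrix"),
                            ploidy_map = NULL,
                            ct_input = "simulate", flow_input = "simulate",
                            height_threshold = 50,
                            size_range = c(120, 480),
                            critical_value = 1.96,
                            midvalue = "mean",
                            n_sites = 1000,
                            sim_mode = "exact_count",
                            calibrator_species = "C. nankingense",
                            irc_gene = "PP2A",
                            irc_ploidies = c(4, 8, 10),
                            efficiency = 2,
                            reference_species = "C. nankingense",
                            seed = 1,
                            out_dir = "ploidymeth-report") {
  msap_format <- match.arg(msap_format)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2],
            height_threshold >= 0, critical_value > 0, efficiency > 1,
            n_sites >= 3)
  midvalue <- match.arg(midvalue, c("mean", "median"))
  if (!is.null(msap_input) && !file.exists(msap_input)) {
    stop(sprintf("msap_input '%s' does not exist", msap_input),
         call. = FALSE)
  }
  for (p in c(ct_input, flow_input)) {
    if (!is.null(p) && !identical(p, "simulate") && !file.exists(p)) {
      stop(sprintf("input '%s' does not exist", p), call. = FALSE)
    }
  }
  structure(
    list(msap_input = msap_input, msap_format = msap_format,
         ploidy_map = ploidy_map, ct_input = ct_input,
         flow_input = flow_input, height_threshold = height_threshold,
         size_range = size_range, critical_value = critical_value,
         midvalue = midvalue, n_sites = as.integer(n_sites),
         sim_mode = sim_mode, calibrator_species = calibrator_species,
         irc_gene = irc_gene, irc_ploidies = irc_ploidies,
         efficiency = efficiency, reference_species = reference_species,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Run the full methylation + expression pipeline
#'
#' Orchestrates score -> filter -> classify -> profile -> statistics ->
#' expression -> report. Writes a TSV report bundle plus a JSON run
#' manifest into the configured output directory and returns the
#' intermediate objects invisibly. Repeated runs with the same
#' configuration and seed produce byte-identical reports; each report
#' carries the configuration hash in a header comment.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `profiles`, `midvalue_u`, `cross_u`,
#'   `correlations`, `summary`, `expression` (or `NULL`), `dna_content`
#'   (or `NULL`), `files` (paths written).
#' @details Any stage failure is re-thrown with the stage name prefixed,
#'   and files already written by the failed run are removed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis-relevant settings; where outputs land is not part
  # of the analysis identity
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config),
                                                  "out_dir")])
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# ploidymeth report; config_hash=%s", cfg_hash),
               con)
    close(con)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    written <<- c(written, path)
    path
  }

  log_stage <- function(...) message(sprintf(...))

  # --- score & classify -------------------------------------------------
  log_stage("stage: score")
  msap <- stage("score", {
    if (is.null(config$msap_input)) {
      tab <- generate_msap(msap_scenario(
        n_sites = config$n_sites, mode = config$sim_mode,
        seed = config$seed
      ))
      ploidy <- attr(tab, "ploidy")
    } else {
      tab <- if (config$msap_format == "peaks") {
        read_peak_table(config$msap_input, config$height_threshold)
      } else {
        read_scored_matrix(config$msap_input)
      }
      ploidy <- config$ploidy_map
      if (is.character(ploidy) && length(ploidy) == 1L) {
        ploidy <- readr::read_csv(ploidy, show_col_types = FALSE)
      }
      if (nrow(tab) == 0) stop("no fragments read from input")
    }
    list(table = tab, ploidy = ploidy)
  })

  log_stage("stage: classify")
  profiles <- stage("classify", {
    msap$table |>
      filter_size_range(config$size_range[1], config$size_range[2]) |>
      filter_reproducible() |>
      build_profiles(msap$ploidy)
  })

  # --- methylation statistics ------------------------------------------
  log_stage("stage: stats")
  stats_out <- stage("stats", {
    mid <- midvalue_comparisons(profiles, config$critical_value,
                                config$midvalue)
    crossed <- cross_ploidy_comparisons(profiles, config$critical_value)
    cors <- purrr::map(meth_measures(), function(m) {
      pearson_ploidy_correlation(profiles, m)
    }) |> purrr::list_rbind()
    list(mid = mid, crossed = crossed, cors = cors,
         summary = summarize_profiles(profiles))
  })

  # --- expression arm ---------------------------------------------------
  expr_fit <- NULL
  if (!is.null(config$ct_input)) {
    log_stage("stage: qpcr")
    expr_fit <- stage("qpcr", {
      ct <- if (identical(config$ct_input, "simulate")) {
        generate_ct(ct_scenario_chrysanthemum(seed = config$seed))
      } else {
        readr::read_csv(config$ct_input, show_col_types = FALSE)
      }
      chained_normalization(
        ct, chrysanthemum_reference_plan()$plan,
        calibrator_species = config$calibrator_species,
        efficiency = config$efficiency,
        irc_gene = config$irc_gene,
        irc_ploidies = config$irc_ploidies
      )
    })
  }

  content <- NULL
  if (!is.null(config$flow_input)) {
    log_stage("stage: flow")
    content <- stage("flow", {
      flow <- if (identical(config$flow_input, "simulate")) {
        generate_flow(seed = config$seed)
      } else {
        readr::read_csv(config$flow_input, show_col_types = FALSE)
      }
      dna_content_ratio(flow, config$reference_species)
    })
  }

  # --- report bundle ----------------------------------------------------
  log_stage("stage: report")
  files <- stage("report", {
    f <- character()
    prof_path <- file.path(config$out_dir, "profiles.tsv")
    con <- file(prof_path, "w")
    writeLines(sprintf("# ploidymeth report; config_hash=%s", cfg_hash),
               con)
    close(con)
    prof_fmt <- profiles |>
      dplyr::transmute(
        sample = .data$sample, ploidy = .data$ploidy,
        non_pct = sprintf("%.1f", 100 * .data$p_non),
        total_pct = sprintf("%.1f", 100 * .data$p_total),
        full_pct = sprintf("%.1f", 100 * .data$p_full),
        hemi_pct = sprintf("%.1f", 100 * .data$p_hemi)
      )
    readr::write_tsv(prof_fmt, prof_path, append = TRUE,
                     col_names = TRUE)
    written <<- c(written, prof_path)
    f <- c(f, prof_path)

    mid_fmt <- stats_out$mid |>
      dplyr::transmute(.data$sample, .data$ploidy, .data$measure,
                       u = sprintf("%.2f", .data$u),
                       significant = .data$significant)
    f <- c(f, emit(mid_fmt, "within_group_u.tsv"))
    cross_fmt <- stats_out$crossed |>
      dplyr::transmute(.data$ploidy_1, .data$ploidy_2, .data$measure,
                       u = sprintf("%.2f", .data$u),
                       significant = .data$significant)
    f <- c(f, emit(cross_fmt, "cross_ploidy_u.tsv"))
    cor_fmt <- stats_out$cors |>
      dplyr::transmute(measure = sub("p_", "", .data$y_label), .data$n,
                       r = sprintf("%.2f", .data$r),
                       r2 = sprintf("%.2f", .data$r2),
                       p_value = signif(.data$p_value, 3))
    f <- c(f, emit(cor_fmt, "ploidy_correlation.tsv"))
    sum_fmt <- stats_out$summary |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                  ~ sprintf("%.1f", .x)))
    f <- c(f, emit(sum_fmt, "profile_summary.tsv"))

    if (!is.null(expr_fit)) {
      expr_fmt <- tidy(expr_fit) |>
        dplyr::transmute(.data$gene, .data$species, .data$ploidy,
                         quantity = sprintf("%.2f", .data$quantity),
                         se = sprintf("%.3f", .data$se), .data$n)
      f <- c(f, emit(expr_fmt, "expression.tsv"))
      f <- c(f, emit(glance(expr_fit), "expression_validity.tsv"))
    }
    if (!is.null(content)) {
      content_fmt <- content |>
        dplyr::mutate(relative_content =
                        sprintf("%.2f", .data$relative_content))
      f <- c(f, emit(content_fmt, "dna_content.tsv"))
      if (!is.null(expr_fit)) {
        corr <- purrr::map(unique(tidy(expr_fit)$gene), function(g) {
          expression_content_correlation(expr_fit, content, g)
        }) |> purrr::list_rbind()
        f <- c(f, emit(corr, "expression_content_correlation.tsv"))
      }
    }

    manifest <- list(
      package = "ploidymeth",
      version = as.character(utils::packageVersion("ploidymeth")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = cfg_hash,
      config = unclass(config),
      outputs = basename(f)
    )
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
    written <<- c(written, manifest_path)
    c(f, manifest_path)
  })

  invisible(list(
    profiles = profiles, midvalue_u = stats_out$mid,
    cross_u = stats_out$crossed, correlations = stats_out$cors,
    summary = stats_out$summary, expression = expr_fit,
    dna_content = content, files = files
  ))
}
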