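#' Default pipeline configuration
#'
#' Nested list accepted by [run_pipeline()], with blocks `simulation`
#' (`amplicon` and `isotope` sub-blocks passed to [amplicon_sim_config()]
#' and [isotope_sim_config()]), `input` (paths to a feature-table TSV trio
#' prefix, a BIOM-JSON file, or an isotope CSV, used instead of
#' simulation), `filtering` ([filter_spec()] arguments), `tests`
#' (correction method, alpha, class labels) and `report`
#' (plausible discrimination range for the qualitative diet call).
#' A YAML file with the same structure is accepted anywhere a config is.
#'
#' @param seed Integer seed forwarded to both simulation blocks.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    simulation = list(
      amplicon = list(seed = seed),
      isotope = list(seed = seed)
    ),
    input = list(),
    filtering = list(),
    tests = list(
      correction = "holm",
      alpha = 0.05,
      focal_class = "unknown",
      herbivore_class = "phytophagous",
      carnivore_class = "aphytophagous"
    ),
    report = list(plausible_delta15N = c(0, 4))
  )
}

#' Qualitative diet call from the two evidence streams
#'
#' Codifies the narrative synthesis of the two analyses into an explicit,
#' fully configurable decision rule (a reporting convention of this
#' package, not an estimator):
#'
#' * if isotope evidence is present and the nitrogen discrimination
#'   implied by a pure-plant diet falls outside the plausible literature
#'   range, the call is `"ambiguous"` regardless of prevalence;
#' * otherwise `"herbivory-consistent"` when the focal class is
#'   indistinguishable from known herbivores (corrected p > alpha) while
#'   differing from known carnivores (corrected p <= alpha);
#' * `"carnivory-consistent"` for the mirrored pattern;
#' * `"ambiguous"` in every other case, including insufficient data.
#'
#' All inputs to the rule are echoed in the returned object.
#'
#' @param focal_vs_herbivore_p,focal_vs_carnivore_p Corrected p-values of
#'   the focal-class prevalence comparisons; `NULL` when unavailable.
#' @param implied_delta15N Nitrogen discrimination (per mil) implied by a
#'   leaf fraction of 1, or `NULL` when no isotope data are present.
#' @param alpha Significance level applied to the corrected p-values.
#' @param plausible_delta15N Inclusive range of discriminations (per mil)
#'   considered plausible for insect herbivores; the default 0-4 spans
#'   published values from low-fractionating caterpillars to a full
#'   trophic step.
#' @return List of class `diet_call` with fields `call` and `inputs`.
#' @export
classify_diet <- function(focal_vs_herbivore_p = NULL,
                          focal_vs_carnivore_p = NULL,
                          implied_delta15N = NULL,
                          alpha = 0.05,
                          plausible_delta15N = c(0, 4)) {
  inputs <- list(focal_vs_herbivore_p = focal_vs_herbivore_p,
                 focal_vs_carnivore_p = focal_vs_carnivore_p,
                 implied_delta15N = implied_delta15N,
                 alpha = alpha,
                 plausible_delta15N = plausible_delta15N)
  call <- "ambiguous"
  iso_implausible <- !is.null(implied_delta15N) &&
    (implied_delta15N < plausible_delta15N[1] ||
     implied_delta15N > plausible_delta15N[2])
  have_prev <- !is.null(focal_vs_herbivore_p) &&
    !is.null(focal_vs_carnivore_p)
  if (!iso_implausible && have_prev) {
    if (focal_vs_herbivore_p > alpha && focal_vs_carnivore_p <= alpha) {
      call <- "herbivory-consistent"
    } else if (focal_vs_carnivore_p > alpha &&
               focal_vs_herbivore_p <= alpha) {
      call <- "carnivory-consistent"
    }
  }
  structure(list(call = call, inputs = inputs), class = "diet_call")
}

#' @export
print.diet_call <- function(x, ...) {
  cat("<diet_call>", x$call, "\n")
  invisible(x)
}

#' Run the combined-evidence pipeline
#'
#' Executes, in order: simulation (when configured), feature-table
#' filtering, chloroplast prevalence, diet-class tests, the isotope mixing
#' model, and the combined evidence report. Every intermediate artifact is
#' written under `output_dir` (TSV/CSV tables, `report.json`,
#' `report.md`, and a `run.log` with versions, seed and thresholds). All
#' numbers in the report are taken verbatim from the upstream result
#' objects. On failure, files already written by the failed run are
#' removed.
#'
#' Either evidence stream may be absent (no simulation block and no input
#' path): the report then carries the other stream alone and the missing
#' section is marked absent.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure.
#' @param output_dir Directory for artifacts; created if needed.
#' @param seed Optional override applied to both simulation blocks.
#' @return List of class `evidence_report` with elements `prevalence`
#'   (summaries and tests), `isotope` (group means, lines, implied
#'   discriminations, tests), `diet_call`, and `paths` of written files.
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile("run_"),
                         seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  def <- default_config()
  # defaults fill in thresholds and labels; the presence or absence of the
  # simulation / input blocks is the caller's, so streams can be omitted
  cfg$tests <- utils::modifyList(def$tests, cfg$tests %||% list())
  cfg$report <- utils::modifyList(def$report, cfg$report %||% list())
  if (!is.null(seed)) {
    if (!is.null(cfg$simulation$amplicon)) cfg$simulation$amplicon$seed <- seed
    if (!is.null(cfg$simulation$isotope)) cfg$simulation$isotope$seed <- seed
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  tryCatch({
    tc <- cfg$tests
    report <- list(prevalence = list(present = FALSE),
                   isotope = list(present = FALSE))

    ## ---- amplicon stream ----
    table <- NULL
    if (!is.null(cfg$input$feature_table_prefix)) {
      table <- read_feature_table(cfg$input$feature_table_prefix)
    } else if (!is.null(cfg$input$biom_path)) {
      table <- read_biom_feature_table(cfg$input$biom_path,
                                       cfg$input$metadata)
    } else if (!is.null(cfg$simulation$amplicon)) {
      acfg <- do.call(amplicon_sim_config, cfg$simulation$amplicon)
      table <- generate_feature_table(acfg)
      note(write_feature_table(table, file.path(output_dir, "simulated")))
    }
    prev <- NULL
    if (!is.null(table)) {
      spec <- do.call(filter_spec, cfg$filtering %||% list())
      filtered <- filter_feature_table(table, spec)
      note(write_feature_table(filtered, file.path(output_dir, "filtered")))
      prev <- chloroplast_proportions(filtered)
      p_path <- file.path(output_dir, "prevalence.csv")
      utils::write.csv(prev, p_path, row.names = FALSE)
      note(p_path)

      summ <- group_summary(prev$proportion, prev$diet_class)
      if (length(unique(prev$diet_class)) < 2) {
        report$prevalence <- list(present = TRUE, summary = summ,
                                  kruskal_wallis = NULL, pairwise = NULL)
        s_path <- file.path(output_dir, "prevalence_summary.csv")
        utils::write.csv(summ, s_path, row.names = FALSE)
        note(s_path)
        skip_tests <- TRUE
      } else {
        skip_tests <- FALSE
      }
      if (!skip_tests) {
      kw <- kruskal_wallis(prev$proportion, prev$diet_class)
      pw <- pairwise_ranksum(prev$proportion, prev$diet_class,
                             correction = tc$correction)
      tests <- rbind(
        data.frame(method = kw$method, groups = kw$groups,
                   statistic = kw$statistic, df = as.character(kw$df),
                   p_value = kw$p_value, p_adjusted = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(method = pw$method, groups = pw$groups,
                   statistic = pw$statistic, df = as.character(pw$df),
                   p_value = pw$p_value, p_adjusted = pw$p_adjusted,
                   stringsAsFactors = FALSE)
      )
      t_path <- file.path(output_dir, "prevalence_tests.csv")
      s_path <- file.path(output_dir, "prevalence_summary.csv")
      utils::write.csv(tests, t_path, row.names = FALSE)
      utils::write.csv(summ, s_path, row.names = FALSE)
      note(c(t_path, s_path))
      report$prevalence <- list(present = TRUE, summary = summ,
                                kruskal_wallis = kw, pairwise = pw)
      }
    }

    ## ---- isotope stream ----
    iso <- NULL
    if (!is.null(cfg$input$isotope_csv)) {
      iso <- read_isotope_csv(cfg$input$isotope_csv)
    } else if (!is.null(cfg$simulation$isotope)) {
      icfg <- do.call(isotope_sim_config, cfg$simulation$isotope)
      iso <- generate_isotope_dataset(icfg)
      note(write_isotope_csv(iso, file.path(output_dir, "isotope.csv")))
    }
    implied_n <- NULL
    if (!is.null(iso) && nrow(iso) > 0) {
      gm <- group_means(iso)
      nline <- fit_mixing_line(iso, "N")
      cline <- fit_mixing_line(iso, "C")
      implied_n <- discrimination_at(nline, 1)
      implied_c <- discrimination_at(cline, 1)
      lines_df <- data.frame(
        element = c("N", "C"),
        intercept = c(nline$intercept, cline$intercept),
        slope = c(nline$slope, cline$slope),
        intercept_se = c(nline$intercept_se, cline$intercept_se),
        slope_se = c(nline$slope_se, cline$slope_se),
        implied_discrimination_at_1 = c(implied_n, implied_c),
        stringsAsFactors = FALSE
      )
      cvl_n <- welch_t(iso$d15N[iso$role == "consumer"],
                       iso$d15N[iso$role == "leaves"])
      cvl_c <- welch_t(iso$d13C[iso$role == "consumer"],
                       iso$d13C[iso$role == "leaves"])
      iso_tests <- rbind(
        cbind(element = "N", comparison = "consumer vs leaves", cvl_n),
        cbind(element = "C", comparison = "consumer vs leaves", cvl_c)
      )
      gm_path <- file.path(output_dir, "isotope_group_means.csv")
      ln_path <- file.path(output_dir, "mixing_lines.csv")
      it_path <- file.path(output_dir, "isotope_tests.csv")
      utils::write.csv(gm, gm_path, row.names = FALSE)
      utils::write.csv(lines_df, ln_path, row.names = FALSE)
      utils::write.csv(iso_tests, it_path, row.names = FALSE)
      note(c(gm_path, ln_path, it_path))
      report$isotope <- list(present = TRUE, group_means = gm,
                             lines = lines_df, tests = iso_tests)
    }

    ## ---- combined call ----
    focal_herb_p <- focal_carn_p <- NULL
    if (!is.null(prev)) {
      pw <- report$prevalence$pairwise
      pick <- function(a, b) {
        hit <- pw$groups %in% paste(c(a, b), c(b, a), sep = " vs ")
        if (any(hit)) pw$p_adjusted[hit][1] else NULL
      }
      focal_herb_p <- pick(tc$focal_class, tc$herbivore_class)
      focal_carn_p <- pick(tc$focal_class, tc$carnivore_class)
    }
    call <- classify_diet(focal_herb_p, focal_carn_p, implied_n,
                          alpha = tc$alpha,
                          plausible_delta15N = cfg$report$plausible_delta15N)
    report$diet_call <- call

    ## ---- serialize ----
    json_path <- file.path(output_dir, "report.json")
    jsonlite::write_json(strip_classes(report), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    note(json_path)
    md_path <- file.path(output_dir, "report.md")
    writeLines(render_report_md(report), md_path)
    note(md_path)
    log_path <- file.path(output_dir, "run.log")
    writeLines(c(
      paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste("R:", R.version.string),
      paste("trophmix:",
            as.character(utils::packageVersion("trophmix"))),
      paste("amplicon seed:", cfg$simulation$amplicon$seed %||% "none"),
      paste("isotope seed:", cfg$simulation$isotope$seed %||% "none"),
      paste("correction:", tc$correction),
      paste("alpha:", tc$alpha),
      paste("plausible delta15N:",
            paste(cfg$report$plausible_delta15N, collapse = "-"))
    ), log_path)
    note(log_path)

    report$paths <- written
    class(report) <- "evidence_report"
    report
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' @export
print.evidence_report <- function(x, ...) {
  cat("<evidence_report>\n")
  cat("  prevalence stream:", if (x$prevalence$present) "present" else "absent",
      "\n")
  cat("  isotope stream:", if (x$isotope$present) "present" else "absent", "\n")
  cat("  diet call:", x$diet_call$call, "\n")
  invisible(x)
}

# drop S3 classes so jsonlite serializes plainly
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    x
  } else if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

render_report_md <- function(report) {
  out <- c("# Combined-evidence diet report", "")
  if (report$prevalence$present) {
    s <- report$prevalence$summary
    kw <- report$prevalence$kruskal_wallis
    out <- c(out, "## Chloroplast prevalence", "",
             sprintf("- %s: n=%d, median %.3f, IQR %.3f",
                     s$group, s$n, s$median, s$iqr))
    if (!is.null(kw)) {
      out <- c(out,
               sprintf("- Kruskal-Wallis: chi-square(%s) = %.3f, p = %.4g",
                       kw$df, kw$statistic, kw$p_value),
               sprintf("- %s (%s): p = %.4g, adjusted p = %.4g",
                       report$prevalence$pairwise$method,
                       report$prevalence$pairwise$groups,
                       report$prevalence$pairwise$p_value,
                       report$prevalence$pairwise$p_adjusted))
    }
    out <- c(out, "")
  } else {
    out <- c(out, "## Chloroplast prevalence", "", "absent", "")
  }
  if (report$isotope$present) {
    l <- report$isotope$lines
    out <- c(out, "## Stable-isotope mixing model", "",
             sprintf(
               "- %s line: fraction = %.2f + %.2f * Delta; implied Delta at fraction 1 = %.1f per mil",
               l$element, l$intercept, l$slope,
               l$implied_discrimination_at_1),
             "")
  } else {
    out <- c(out, "## Stable-isotope mixing model", "", "absent", "")
  }
  ci <- report$diet_call$inputs
  c(out, "## Qualitative diet call", "",
    sprintf("- call: **%s**", report$diet_call$call),
    sprintf("- thresholds: alpha = %g; plausible Delta15N = [%g, %g] per mil",
            ci$alpha, ci$plausible_delta15N[1], ci$plausible_delta15N[2]),
    sprintf("- focal vs herbivores adjusted p: %s",
            if (is.null(ci$focal_vs_herbivore_p)) "absent"
            else format(ci$focal_vs_herbivore_p, digits = 4)),
    sprintf("- focal vs carnivores adjusted p: %s",
            if (is.null(ci$focal_vs_carnivore_p)) "absent"
            else format(ci$focal_vs_carnivore_p, digits = 4)),
    sprintf("- implied Delta15N at fraction 1: %s",
            if (is.null(ci$implied_delta15N)) "absent"
            else sprintf("%.2f per mil", ci$implied_delta15N)))
}
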