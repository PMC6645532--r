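#' Trophic discrimination (fractionation)
#'
#' The consumer-minus-diet difference in an isotope ratio,
#' `Delta = delta_consumer - delta_diet` (per mil). Typical nitrogen values
#' run around 3-4 per mil per full trophic step, but are substantially
#' lower in many herbivorous insects.
#'
#' @param consumer_delta,diet_delta Finite delta values (per mil).
#' @return Discrimination in per mil; vectorized.
#' @examples
#' discrimination(3.74, 2.13) # 1.61
#' @export
discrimination <- function(consumer_delta, diet_delta) {
  stopifnot(all(is.finite(consumer_delta)), all(is.finite(diet_delta)))
  consumer_delta - diet_delta
}

#' Two-source mixing model, forward direction
#'
#' Expected consumer delta value given a diet that mixes two isotopic
#' sources and a single trophic discrimination:
#' `fraction * source1 + (1 - fraction) * source2 + discrimination`.
#' Discrimination is assumed constant across the two sources, so the model
#' has one discrimination parameter per element.
#'
#' @param fraction Diet fraction from source 1, normally in \[0, 1\].
#'   Values outside the interval are allowed with a warning, for
#'   sensitivity use.
#' @param delta_source1,delta_source2 Source mean delta values (per mil).
#' @param discrimination Trophic discrimination (per mil).
#' @return Consumer delta value (per mil); vectorized over `fraction`.
#' @export
mixing_forward <- function(fraction, delta_source1, delta_source2,
                           discrimination) {
  if (any(fraction < 0 | fraction > 1)) {
    warning("diet fraction outside [0, 1]; evaluating the model anyway",
            call. = FALSE)
  }
  fraction * delta_source1 + (1 - fraction) * delta_source2 + discrimination
}

#' Invert the mixing model to a fraction-discrimination line
#'
#' Solving the two-source model for the diet fraction gives a linear
#' relation between the fraction and the (unknown) discrimination:
#' `fraction = (consumer - source2 - Delta) / (source1 - source2)`,
#' i.e. `fraction = intercept + slope * Delta` with
#' `intercept = (consumer - source2) / (source1 - source2)` and
#' `slope = -1 / (source1 - source2)` (per per-mil). The line is the
#' diagnostic object of the analysis: reading it at a plausible
#' discrimination yields the implied diet fraction, and reading it at
#' fraction 1 yields the discrimination implied by pure source-1 feeding.
#'
#' @param consumer_mean Mean consumer delta (per mil).
#' @param source1_mean,source2_mean Source mean deltas (per mil); must
#'   differ, otherwise the fraction is unidentifiable.
#' @param element `"N"` or `"C"`, a consistency tag carried on the line.
#' @param source_labels Length-2 character, names of sources 1 and 2.
#' @param se Optional named numeric with standard errors of the three
#'   means (`consumer`, `source1`, `source2`); when supplied,
#'   delta-method standard errors of the intercept and slope are attached.
#' @return An object of class `mixing_line` with fields `intercept`,
#'   `slope`, `element`, `source_labels`, the three means, and (when `se`
#'   is given) `intercept_se` and `slope_se`.
#' @examples
#' mixing_line(3.74, 2.13, 4.12, "N") # intercept 0.19, slope 0.50
#' @export
mixing_line <- function(consumer_mean, source1_mean, source2_mean,
                        element = c("N", "C"),
                        source_labels = c("source1", "source2"),
                        se = NULL) {
  element <- match.arg(element)
  stopifnot(is.finite(consumer_mean), is.finite(source1_mean),
            is.finite(source2_mean))
  denom <- source1_mean - source2_mean
  if (denom == 0) {
    stop("degenerate mixing model: the two source means are equal, ",
         "the diet fraction is unidentifiable", call. = FALSE)
  }
  line <- structure(
    list(intercept = (consumer_mean - source2_mean) / denom,
         slope = -1 / denom,
         element = element,
         source_labels = source_labels,
         consumer_mean = consumer_mean,
         source1_mean = source1_mean,
         source2_mean = source2_mean),
    class = "mixing_line"
  )
  if (!is.null(se)) {
    stopifnot(all(c("consumer", "source1", "source2") %in% names(se)))
    # delta method on intercept = (mc - m2)/(m1 - m2), slope = -1/(m1 - m2)
    dI <- c(consumer = 1 / denom,
            source1 = -(consumer_mean - source2_mean) / denom^2,
            source2 = (consumer_mean - source1_mean) / denom^2)
    dS <- c(consumer = 0,
            source1 = 1 / denom^2,
            source2 = -1 / denom^2)
    se <- se[c("consumer", "source1", "source2")]
    line$intercept_se <- sqrt(sum((dI * se)^2))
    line$slope_se <- sqrt(sum((dS * se)^2))
  }
  line
}

#' @export
print.mixing_line <- function(x, digits = 2, ...) {
  cat(sprintf("<mixing_line> %s: fraction = %.*f + %.*f * Delta%s\n",
              x$element, digits, x$intercept, digits, x$slope,
              if (x$element == "N") "15N" else "13C"))
  cat(sprintf("  sources: %s (fraction) vs %s\n",
              x$source_labels[1], x$source_labels[2]))
  if (!is.null(x$intercept_se)) {
    cat(sprintf("  se: intercept %.3g, slope %.3g\n",
                x$intercept_se, x$slope_se))
  }
  invisible(x)
}

#' Diet fraction implied by a discrimination value
#'
#' Evaluates a [mixing_line()] at a discrimination Delta:
#' `intercept + slope * Delta`. Values outside \[0, 1\] are returned
#' unclamped — the line is used as a diagnostic over a range of plausible
#' discriminations, and truncation would hide the implausibility — with an
#' `out_of_range` attribute flagging them.
#'
#' @param line A [mixing_line()].
#' @param discrimination Discrimination value(s), per mil.
#' @return Numeric fraction(s) with logical attribute `out_of_range`.
#' @export
fraction_at <- function(line, discrimination) {
  stopifnot(inherits(line, "mixing_line"))
  f <- line$intercept + line$slope * discrimination
  attr(f, "out_of_range") <- f < 0 | f > 1
  f
}

#' Discrimination implied by a diet fraction
#'
#' Inverse reading of the line: `Delta = (fraction - intercept) / slope`.
#' At `fraction = 1` this is the discrimination implied by a pure
#' source-1 (host-plant-only) diet — the quantity compared against
#' literature discrimination ranges.
#'
#' @param line A [mixing_line()].
#' @param fraction Diet fraction(s).
#' @return Discrimination value(s) in per mil.
#' @export
discrimination_at <- function(line, fraction) {
  stopifnot(inherits(line, "mixing_line"))
  if (line$slope == 0) {
    stop("degenerate mixing line: zero slope", call. = FALSE)
  }
  (as.numeric(fraction) - line$intercept) / line$slope
}

#' Per-role isotope group means
#'
#' Arithmetic mean, sd and n of `d15N` and `d13C` for each requested role.
#' A role with a single measurement reports `sd = 0` (flagged by `n = 1`).
#'
#' @param data Isotope data frame (columns `role`, `d15N`, `d13C`).
#' @param roles Roles to summarize; default, all present.
#' @return Data frame with one row per role: `role`, `n`, `mean_d15N`,
#'   `sd_d15N`, `mean_d13C`, `sd_d13C`.
#' @export
group_means <- function(data, roles = unique(data$role)) {
  missing <- setdiff(roles, unique(data$role))
  if (length(missing) > 0) {
    stop("no measurements for role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(roles, function(r) {
    d <- data[data$role == r, , drop = FALSE]
    data.frame(role = r, n = nrow(d),
               mean_d15N = mean(d$d15N),
               sd_d15N = if (nrow(d) > 1) stats::sd(d$d15N) else 0,
               mean_d13C = mean(d$d13C),
               sd_d13C = if (nrow(d) > 1) stats::sd(d$d13C) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit a mixing line from measured isotope data
#'
#' Computes role means with [group_means()] and builds the
#' fraction-discrimination line for one element, attaching delta-method
#' standard errors of the intercept and slope derived from the standard
#' errors of the three role means.
#'
#' @param data Isotope data frame (columns `role`, `d15N`, `d13C`).
#' @param element `"N"` or `"C"`.
#' @param consumer_role,source1_role,source2_role Role labels; source 1 is
#'   the role whose diet fraction the line describes (leaves, by default).
#' @return A [mixing_line()] with standard errors.
#' @export
fit_mixing_line <- function(data, element = c("N", "C"),
                            consumer_role = "consumer",
                            source1_role = "leaves",
                            source2_role = "larvae") {
  element <- match.arg(element)
  gm <- group_means(data, c(consumer_role, source1_role, source2_role))
  col_mean <- if (element == "N") "mean_d15N" else "mean_d13C"
  col_sd <- if (element == "N") "sd_d15N" else "sd_d13C"
  m <- stats::setNames(gm[[col_mean]], gm$role)
  se <- stats::setNames(gm[[col_sd]] / sqrt(gm$n), gm$role)
  mixing_line(m[[consumer_role]], m[[source1_role]], m[[source2_role]],
              element = element,
              source_labels = c(source1_role, source2_role),
              se = c(consumer = se[[consumer_role]],
                     source1 = se[[source1_role]],
                     source2 = se[[source2_role]]))
}

#' Reference group means for the lycaenid / host-tree / ant study system
#'
#' Published mean delta values for the system this pipeline was built
#' around: *Anthene usamba* caterpillar cuticles (the consumer),
#' *Vachellia drepanolobium* leaves and *Crematogaster mimosae* ant larvae
#' (the two candidate diet sources). Units are per mil, nitrogen relative
#' to atmospheric air and carbon relative to VPDB. These are the inputs of
#' the worked mixing-line example: the nitrogen line
#' `p = 0.19 + 0.50 * Delta15N` and the carbon line
#' `q = -0.55 + 0.55 * Delta13C`.
#'
#' @return Data frame with columns `role`, `d15N`, `d13C`.
#' @examples
#' gm <- reference_group_means()
#' nl <- mixing_line(gm$d15N[gm$role == "consumer"],
#'                   gm$d15N[gm$role == "leaves"],
#'                   gm$d15N[gm$role == "larvae"], "N")
#' discrimination_at(nl, 1) # ~1.6 per mil implied by a pure-leaf diet
#' @export
reference_group_means <- function() {
  data.frame(
    role = c("consumer", "leaves", "larvae"),
    d15N = c(3.74, 2.13, 4.12),
    d13C = c(-25.5, -28.3, -26.5),
    stringsAsFactors = FALSE
  )
}
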