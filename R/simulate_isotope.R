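#' Configuration for simulated stable-isotope datasets
#'
#' Generative reading of the two-source mixing model: a consumer's expected
#' delta value is a diet-fraction-weighted average of the two source means
#' plus a trophic discrimination, and measurements scatter around the
#' expectation with Gaussian noise. Defaults use the reference group means
#' of the lycaenid / host-tree / ant system (see
#' [reference_group_means()]): leaves delta15N 2.13 / delta13C -28.3,
#' ant larvae 4.12 / -26.5, true discriminations 1.61 and 2.8 per mil,
#' measurement noise 0.5 per mil, and per-role sample counts 17 consumers,
#' 47 leaves, 20 larvae.
#'
#' @param true_p Fraction of assimilated nitrogen derived from leaves, in
#'   \[0, 1\].
#' @param true_q Fraction of assimilated carbon derived from leaves, in
#'   \[0, 1\].
#' @param delta15N_frac,delta13C_frac True trophic discrimination values
#'   (per mil) added to the consumer's mixture mean.
#' @param source_means Named list with entries `leaves` and `larvae`, each
#'   `c(d15N = ..., d13C = ...)` (per mil).
#' @param source_sds,consumer_sd Gaussian noise scales (per mil), >= 0.
#' @param n_per_role Named integer vector with entries `consumer`,
#'   `leaves`, `larvae`; a role may be 0 (no rows generated).
#' @param seed Integer seed; per-role substreams are derived
#'   deterministically so enlarging one role leaves the others unchanged.
#' @return An object of class `isotope_sim_config`.
#' @export
isotope_sim_config <- function(true_p = 1,
                               true_q = 1,
                               delta15N_frac = 1.61,
                               delta13C_frac = 2.8,
                               source_means = list(
                                 leaves = c(d15N = 2.13, d13C = -28.3),
                                 larvae = c(d15N = 4.12, d13C = -26.5)),
                               source_sds = c(leaves = 0.5, larvae = 0.5),
                               consumer_sd = 0.5,
                               n_per_role = c(consumer = 17, leaves = 47,
                                              larvae = 20),
                               seed = 1L) {
  if (true_p < 0 || true_p > 1 || true_q < 0 || true_q > 1) {
    stop("`true_p` and `true_q` must lie in [0, 1]", call. = FALSE)
  }
  if (any(source_sds < 0) || consumer_sd < 0) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  for (r in c("leaves", "larvae")) {
    if (is.null(source_means[[r]]) ||
        !all(c("d15N", "d13C") %in% names(source_means[[r]]))) {
      stop("`source_means$", r, "` must supply d15N and d13C", call. = FALSE)
    }
  }
  if (!all(c("consumer", "leaves", "larvae") %in% names(n_per_role))) {
    stop("`n_per_role` must name consumer, leaves and larvae", call. = FALSE)
  }
  structure(
    list(true_p = true_p, true_q = true_q,
         delta15N_frac = delta15N_frac, delta13C_frac = delta13C_frac,
         source_means = source_means,
         source_sds = source_sds, consumer_sd = consumer_sd,
         n_per_role = as.integer(n_per_role[c("consumer", "leaves",
                                              "larvae")]) |>
           stats::setNames(c("consumer", "leaves", "larvae")),
         seed = as.integer(seed)),
    class = "isotope_sim_config"
  )
}

#' Generate a synthetic stable-isotope dataset
#'
#' Source roles (`leaves`, `larvae`) are drawn as their configured means
#' plus Gaussian noise; the consumer role is drawn around the two-source
#' mixture mean
#' `true_p * leaves + (1 - true_p) * larvae + delta15N_frac` for nitrogen
#' (and the `true_q` analogue for carbon). With all noise scales zero the
#' consumer values equal the mixture means exactly, which is what makes the
#' analytic round trip through [mixing_line()] and [fraction_at()] testable
#' to machine precision.
#'
#' @param cfg An [isotope_sim_config()].
#' @return Data frame with columns `sample_id`, `role`, `species`, `d15N`,
#'   `d13C`, `pairing_id` (NA; populated only by designs with matched
#'   consumer/source samples from one tree).
#' @export
generate_isotope_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "isotope_sim_config"))
  mu_consumer <- c(
    d15N = cfg$true_p * cfg$source_means$leaves[["d15N"]] +
      (1 - cfg$true_p) * cfg$source_means$larvae[["d15N"]] +
      cfg$delta15N_frac,
    d13C = cfg$true_q * cfg$source_means$leaves[["d13C"]] +
      (1 - cfg$true_q) * cfg$source_means$larvae[["d13C"]] +
      cfg$delta13C_frac
  )
  role_mu <- list(consumer = mu_consumer,
                  leaves = cfg$source_means$leaves,
                  larvae = cfg$source_means$larvae)
  role_sd <- c(consumer = cfg$consumer_sd,
               leaves = cfg$source_sds[["leaves"]],
               larvae = cfg$source_sds[["larvae"]])
  species_of <- c(consumer = "sim_consumer", leaves = "sim_host_plant",
                  larvae = "sim_ant_larvae")
  rows <- list()
  for (ri in seq_along(role_mu)) {
    role <- names(role_mu)[ri]
    n <- cfg$n_per_role[[role]]
    if (n == 0) next
    set.seed((cfg$seed + 1000000L * ri) %% .Machine$integer.max)
    rows[[role]] <- data.frame(
      sample_id = sprintf("%s_%03d", role, seq_len(n)),
      role = role,
      species = species_of[[role]],
      d15N = role_mu[[role]][["d15N"]] + stats::rnorm(n, 0, role_sd[[role]]),
      d13C = role_mu[[role]][["d13C"]] + stats::rnorm(n, 0, role_sd[[role]]),
      pairing_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0) {
    data.frame(sample_id = character(0), role = character(0),
               species = character(0), d15N = numeric(0), d13C = numeric(0),
               pairing_id = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Write / read an isotope measurement table
#'
#' Plain CSV with columns `sample_id`, `role`, `species`, `d15N`, `d13C`,
#' `pairing_id`.
#'
#' @param data Data frame as returned by [generate_isotope_dataset()].
#' @param path CSV file path.
#' @return `write_isotope_csv()` returns `path` invisibly;
#'   `read_isotope_csv()` returns the data frame.
#' @export
write_isotope_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotope_csv
#' @export
read_isotope_csv <- function(path) {
  need <- c("sample_id", "role", "d15N", "d13C")
  if (!file.exists(path)) {
    stop("isotope CSV not found: ", path, call. = FALSE)
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop("isotope CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(out$d15N)) || !all(is.finite(out$d13C))) {
    stop("isotope CSV ", path, " contains non-finite delta values",
         call. = FALSE)
  }
  if (is.null(out$pairing_id)) out$pairing_id <- NA_character_
  out
}
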