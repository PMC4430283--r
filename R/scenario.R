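#' Describe a multi-population demographic history
#'
#' A scenario is a set of named demes with present-day haploid effective
#' sizes plus an ordered event list running backwards in time (years; one
#' generation per year). Events are added with [ev_split()], [ev_resize()],
#' [ev_admixture()] and [ev_growth()].
#'
#' @param demes Named numeric vector of present-day haploid effective sizes.
#' @param label Optional scenario label.
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(demes, label = "scenario") {
  stopifnot(is.numeric(demes), !is.null(names(demes)), all(demes > 0))
  structure(list(demes = demes,
                 events = tibble(time = numeric(), type = character(),
                                 deme = character(), dest = character(),
                                 dest2 = character(), value = numeric()),
                 label = label),
            class = "demographic_scenario")
}

add_event <- function(scn, time, type, deme, dest = NA, dest2 = NA,
                      value = NA_real_) {
  stopifnot(inherits(scn, "demographic_scenario"), time >= 0)
  for (d in stats::na.omit(c(deme, dest, dest2)))
    if (!d %in% names(scn$demes)) stop("unknown deme '", d, "'")
  scn$events <- bind_rows(scn$events,
                          tibble(time = time, type = type, deme = deme,
                                 dest = as.character(dest),
                                 dest2 = as.character(dest2), value = value))
  scn$events <- arrange(scn$events, .data$time)
  scn
}

#' @rdname demographic_scenario
#' @param scn A `demographic_scenario`.
#' @param time Event time in years before present.
#' @param deme,into,source2 Deme names.
#' @export
ev_split <- function(scn, time, deme, into)
  add_event(scn, time, "split", deme, dest = into)

#' @rdname demographic_scenario
#' @param size New haploid effective size (looking further into the past).
#' @export
ev_resize <- function(scn, time, deme, size) {
  stopifnot(size > 0)
  add_event(scn, time, "resize", deme, value = size)
}

#' @rdname demographic_scenario
#' @param proportion Probability that a lineage in `deme` traces back to
#'   `into`; with probability `1 - proportion` it traces to `source2`.
#' @export
ev_admixture <- function(scn, time, deme, into, source2, proportion) {
  stopifnot(proportion >= 0, proportion <= 1)
  add_event(scn, time, "admixture", deme, dest = into, dest2 = source2,
            value = proportion)
}

#' @rdname demographic_scenario
#' @param rate Exponential growth rate per year (forward in time; sizes
#'   shrink at this rate looking backwards).
#' @export
ev_growth <- function(scn, time, deme, rate)
  add_event(scn, time, "growth", deme, value = rate)

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("<demographic_scenario> ", x$label, ": ", length(x$demes),
      " demes (", paste(names(x$demes), collapse = ", "), "), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Validate that a scenario routes all sampled lineages to a common ancestor
#'
#' Checks that event times are admissible, that no event refers to a deme
#' already closed by an earlier split/admixture, and that after all events a
#' single deme remains open (so lineages cannot be stranded).
#'
#' @param scn A [demographic_scenario()].
#' @param sampled Character vector of demes carrying samples
#'   (default: all demes).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_scenario <- function(scn, sampled = names(scn$demes)) {
  open <- setNames(rep(TRUE, length(scn$demes)), names(scn$demes))
  ev <- scn$events
  for (i in seq_len(nrow(ev))) {
    involved <- stats::na.omit(c(ev$deme[i], ev$dest[i], ev$dest2[i]))
    involved <- involved[involved != "NA"]
    if (!all(open[involved]))
      stop("scenario '", scn$label, "': event ", i, " (", ev$type[i],
           " at t=", ev$time[i], ") refers to a closed deme")
    if (ev$type[i] %in% c("split", "admixture")) open[ev$deme[i]] <- FALSE
  }
  if (sum(open) > 1)
    stop("scenario '", scn$label, "': lineages stranded; demes ",
         paste(names(open)[open], collapse = ", "),
         " are never joined into a single ancestral deme")
  invisible(TRUE)
}

# numeric encoding consumed by the C++ engine
scenario_matrix <- function(scn) {
  idx <- setNames(seq_along(scn$demes), names(scn$demes))
  ev <- scn$events
  typ <- c(split = 1, resize = 2, admixture = 3, growth = 4)
  m <- cbind(time = ev$time,
             type = unname(typ[ev$type]),
             d1 = unname(idx[ev$deme]),
             d2 = ifelse(is.na(ev$dest), 0, idx[ev$dest]),
             d3 = ifelse(is.na(ev$dest2), 0, idx[ev$dest2]),
             x = ifelse(is.na(ev$value), 0, ev$value))
  m[is.na(m)] <- 0
  m
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
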