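# Even-odd point-in-polygon with on-edge points included.
# x, y: event coordinates (transformed); vx, vy: polygon vertices.
points_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- (y1 > y) != (y2 > y)
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- logical(length(x))
      flip[crosses] <- x[crosses] < xint
      inside <- xor(inside, flip)
    }
    # exact collinearity + bounding box => point on the closed edge
    d <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (d == 0 &
                            x >= pmin(x1, x2) & x <= pmax(x1, x2) &
                            y >= pmin(y1, y2) & y <= pmax(y1, y2))
    j <- i
  }
  inside | on_edge
}

#' Apply a single gate to an event table
#'
#' Evaluates the gate geometry (under its display transform) on the events
#' listed in `parent` and returns the member event ids. Boundary convention:
#' lower bounds inclusive, upper bounds exclusive; polygon membership by the
#' even-odd rule with on-edge points included; quadrant `+` means `>=` the
#' split.
#'
#' @param table An [event_table()].
#' @param g A [gate()].
#' @param parent Integer vector of parent event ids (default: all events).
#' @return For non-quadrant gates, an integer vector of member event ids (a
#'   subset of `parent`, in `parent` order). For quadrant gates, a named list
#'   of four id vectors (`++`, `+-`, `-+`, `--`) that partition `parent`.
#' @export
apply_gate <- function(table, g, parent = NULL) {
  stopifnot(inherits(table, "event_table"), inherits(g, "gate"))
  missing <- setdiff(g$channels, names(table))
  if (length(missing)) {
    stop(sprintf("gate '%s': channel '%s' missing from table", g$name, missing[1]),
         call. = FALSE)
  }
  if (is.null(parent)) {
    rows <- seq_len(nrow(table))
  } else {
    rows <- match(parent, table$event_id)
    if (anyNA(rows)) stop("parent contains event ids absent from the table", call. = FALSE)
  }
  ids <- table$event_id[rows]
  vals <- lapply(seq_along(g$channels), function(k) {
    tf <- channel_transform(g$transform, g$channels[k])
    tf(table[[g$channels[k]]][rows])
  })
  geo <- g$geometry
  if (g$kind == "quadrant") {
    xp <- vals[[1]] >= geo$x_at
    yp <- vals[[2]] >= geo$y_at
    return(list("++" = ids[xp & yp], "+-" = ids[xp & !yp],
                "-+" = ids[!xp & yp], "--" = ids[!xp & !yp]))
  }
  keep <- switch(g$kind,
    interval = vals[[1]] >= geo$lo & vals[[1]] < geo$hi,
    threshold = if (geo$side == "above") vals[[1]] >= geo$at else vals[[1]] < geo$at,
    rectangle = vals[[1]] >= geo$xlim[1] & vals[[1]] < geo$xlim[2] &
      vals[[2]] >= geo$ylim[1] & vals[[2]] < geo$ylim[2],
    polygon = points_in_polygon(vals[[1]], vals[[2]],
                                geo$vertices[, 1], geo$vertices[, 2])
  )
  ids[keep]
}

#' Apply a gating strategy to an event table
#'
#' Walks the strategy tree from the root, recording the member event ids and
#' counts of every population, and reports each population's fraction of the
#' declared denominator population. An empty denominator yields `NA`
#' fractions with a warning (never silent zeros).
#'
#' @param table An [event_table()].
#' @param strategy A [gating_strategy()].
#' @return An object of class `gating_result` with components `frequencies`
#'   (data frame: population, count, fraction, denominator), `membership`
#'   (named list of event-id vectors) and `strategy`.
#' @export
apply_strategy <- function(table, strategy) {
  stopifnot(inherits(table, "event_table"), inherits(strategy, "gating_strategy"))
  membership <- list()
  membership[[strategy$root]] <- table$event_id
  for (e in strategy$entries) {
    parent_ids <- membership[[e$parent]]
    res <- apply_gate(table, e$gate, parent = parent_ids)
    if (e$gate$kind == "quadrant") {
      names(res) <- e$children
      membership <- c(membership, res)
    } else {
      membership[[e$children]] <- res
    }
  }
  counts <- vapply(membership, length, integer(1))
  denom_n <- counts[[strategy$denominator]]
  if (denom_n == 0L) {
    warning(sprintf("denominator population '%s' is empty; fractions undefined",
                    strategy$denominator), call. = FALSE)
    fractions <- rep(NA_real_, length(counts))
  } else {
    fractions <- unname(counts) / denom_n
  }
  freq <- data.frame(population = names(counts), count = unname(counts),
                     fraction = fractions,
                     denominator = strategy$denominator,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(frequencies = freq, membership = membership,
                 strategy = strategy, n_events = nrow(table)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %d events, denominator '%s' (n = %d)\n",
              x$n_events, x$strategy$denominator,
              population_count(x, x$strategy$denominator)))
  print(x$frequencies, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Population count and fraction accessors
#'
#' @param result A `gating_result` from [apply_strategy()].
#' @param population Population name.
#' @return `population_count()` the event count; `population_fraction()` the
#'   fraction of the strategy's denominator population.
#' @export
population_count <- function(result, population) {
  stopifnot(inherits(result, "gating_result"))
  i <- match(population, result$frequencies$population)
  if (is.na(i)) stop(sprintf("population '%s' not in result", population), call. = FALSE)
  result$frequencies$count[i]
}

#' @rdname population_count
#' @export
population_fraction <- function(result, population) {
  stopifnot(inherits(result, "gating_result"))
  i <- match(population, result$frequencies$population)
  if (is.na(i)) stop(sprintf("population '%s' not in result", population), call. = FALSE)
  result$frequencies$fraction[i]
}
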