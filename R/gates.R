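#' Construct a geometric gate
#'
#' A gate is a named geometric region over one or two channels, interpreted
#' after applying a per-channel display transform. Supported kinds:
#'
#' * `interval` — one channel, membership `lo <= x < hi`.
#' * `threshold` — one channel, `side = "above"` keeps `x >= at`, `"below"`
#'   keeps `x < at`.
#' * `rectangle` — two channels, `xlim`/`ylim` with the lower bound inclusive
#'   and the upper bound exclusive on both axes.
#' * `polygon` — two channels, `vertices` an n x 2 matrix (n >= 3); membership
#'   by the even-odd rule with points exactly on an edge included.
#' * `quadrant` — two channels split at `(x_at, y_at)`; yields exactly four
#'   child populations in the order `++`, `+-`, `-+`, `--` where `+` means
#'   value >= split on that axis (x first).
#'
#' Boundary conventions are fixed (lower inclusive, upper exclusive; `+` is
#' `>=`) so that gating is deterministic and the quadrant children always
#' partition the parent exactly.
#'
#' @param name Gate identifier.
#' @param kind One of `"interval"`, `"threshold"`, `"rectangle"`, `"polygon"`,
#'   `"quadrant"`.
#' @param channels One or two channel names, per kind.
#' @param lo,hi Interval bounds.
#' @param at,side Threshold split point and kept side.
#' @param xlim,ylim Rectangle bounds, each `c(lo, hi)`.
#' @param vertices Polygon vertices, n x 2 numeric matrix.
#' @param x_at,y_at Quadrant split point.
#' @param transform Per-channel display transform under which the geometry is
#'   interpreted: `NULL`/`"identity"`, `"log10"`, `"asinh"`, a
#'   `list(type =, cofactor =)`, or a named list of such specs keyed by
#'   channel.
#' @return An object of class `gate`.
#' @export
#' @examples
#' g <- gate("lymph", "rectangle", c("FSC_A", "SSC_A"),
#'           xlim = c(2e4, 8e4), ylim = c(0, 3e4))
gate <- function(name, kind, channels,
                 lo = NULL, hi = NULL, at = NULL, side = c("above", "below"),
                 xlim = NULL, ylim = NULL, vertices = NULL,
                 x_at = NULL, y_at = NULL, transform = NULL) {
  kind <- match.arg(kind, c("interval", "threshold", "rectangle", "polygon", "quadrant"))
  stopifnot(is.character(name), nzchar(name), is.character(channels))
  geom <- switch(kind,
    interval = {
      if (length(channels) != 1L) stop("interval gate needs 1 channel", call. = FALSE)
      stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
      list(lo = lo, hi = hi)
    },
    threshold = {
      if (length(channels) != 1L) stop("threshold gate needs 1 channel", call. = FALSE)
      stopifnot(is.numeric(at))
      list(at = at, side = match.arg(side))
    },
    rectangle = {
      if (length(channels) != 2L) stop("rectangle gate needs 2 channels", call. = FALSE)
      stopifnot(length(xlim) == 2L, length(ylim) == 2L, xlim[1] < xlim[2], ylim[1] < ylim[2])
      list(xlim = as.numeric(xlim), ylim = as.numeric(ylim))
    },
    polygon = {
      if (length(channels) != 2L) stop("polygon gate needs 2 channels", call. = FALSE)
      vertices <- as.matrix(vertices)
      if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
        stop("polygon needs >= 3 vertices as an n x 2 matrix", call. = FALSE)
      }
      storage.mode(vertices) <- "double"
      if (!all(is.finite(vertices))) stop("polygon vertices must be finite", call. = FALSE)
      list(vertices = vertices)
    },
    quadrant = {
      if (length(channels) != 2L) stop("quadrant gate declares exactly 2 channels", call. = FALSE)
      stopifnot(is.numeric(x_at), is.numeric(y_at))
      list(x_at = x_at, y_at = y_at)
    }
  )
  structure(list(name = name, kind = kind, channels = channels,
                 geometry = geom, transform = transform),
            class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("<gate> %s: %s on (%s)\n", x$name, x$kind,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

QUADRANT_SUFFIXES <- c("++", "+-", "-+", "--")

#' Assemble a hierarchical gating strategy
#'
#' A gating strategy is a rooted tree of populations: each entry attaches a
#' [gate()] to a parent population and names the child population(s) it
#' defines. Quadrant gates define exactly four children (auto-named
#' `<parent><suffix>` with suffixes `++`, `+-`, `-+`, `--` when `children` is
#' omitted); all other gates define one child.
#'
#' Validation rejects duplicate population names, unknown parents and any
#' configuration whose population graph is not a tree.
#'
#' @param root Name of the root population (all events).
#' @param entries List of entries `list(parent =, gate =, child =)` (or
#'   `children =` for quadrants).
#' @param denominator Population whose event count is the denominator for
#'   reported fractions; defaults to the root.
#' @return An object of class `gating_strategy`.
#' @export
gating_strategy <- function(root = "all", entries = list(), denominator = root) {
  stopifnot(is.character(root), nzchar(root), is.list(entries))
  populations <- root
  parents <- character(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!inherits(e$gate, "gate")) stop(sprintf("entry %d has no gate", i), call. = FALSE)
    if (is.null(e$parent)) stop(sprintf("entry %d has no parent", i), call. = FALSE)
    if (!e$parent %in% populations) {
      stop(sprintf("entry %d ('%s'): unknown parent population '%s'",
                   i, e$gate$name, e$parent), call. = FALSE)
    }
    if (e$gate$kind == "quadrant") {
      kids <- e$children
      if (is.null(kids)) kids <- paste0(e$parent, QUADRANT_SUFFIXES)
      if (length(kids) != 4L) stop(sprintf("entry %d: quadrant gate must yield exactly 4 children", i), call. = FALSE)
    } else {
      kids <- e$child
      if (is.null(kids) || length(kids) != 1L) {
        stop(sprintf("entry %d: gate must name exactly 1 child", i), call. = FALSE)
      }
    }
    dup <- kids[kids %in% populations]
    if (length(dup)) stop(sprintf("duplicate population name '%s'", dup[1]), call. = FALSE)
    populations <- c(populations, kids)
    parents[kids] <- e$parent
    entries[[i]]$children <- kids
  }
  if (!denominator %in% populations) {
    stop(sprintf("denominator population '%s' not defined", denominator), call. = FALSE)
  }
  # every non-root population has exactly one parent and is reachable from the
  # root by construction (parents must pre-exist), so the graph is a tree
  structure(list(root = root, entries = entries, populations = populations,
                 parents = parents, denominator = denominator),
            class = "gating_strategy")
}

#' @export
print.gating_strategy <- function(x, ...) {
  cat(sprintf("<gating_strategy> %d populations, root '%s', denominator '%s'\n",
              length(x$populations), x$root, x$denominator))
  depth <- function(p) {
    d <- 0
    while (p != x$root) { p <- x$parents[[p]]; d <- d + 1 }
    d
  }
  for (p in x$populations) {
    cat(strrep("  ", depth(p)), p, "\n", sep = "")
  }
  invisible(x)
}

# ---- serialization -------------------------------------------------------

gate_to_config <- function(g) {
  out <- list(name = g$name, kind = g$kind, channels = as.list(g$channels))
  geo <- g$geometry
  out <- c(out, switch(g$kind,
    interval = list(lo = geo$lo, hi = geo$hi),
    threshold = list(at = geo$at, side = geo$side),
    rectangle = list(xlim = as.list(geo$xlim), ylim = as.list(geo$ylim)),
    polygon = list(vertices = lapply(seq_len(nrow(geo$vertices)),
                                     function(i) as.list(unname(geo$vertices[i, ])))),
    quadrant = list(x_at = geo$x_at, y_at = geo$y_at)
  ))
  if (!is.null(g$transform)) out$transform <- g$transform
  out
}

gate_from_config <- function(cfg) {
  kind <- cfg$kind
  if (is.null(kind)) stop("gate config lacks 'kind'", call. = FALSE)
  verts <- NULL
  if (identical(kind, "polygon")) {
    if (is.null(cfg$vertices)) stop("polygon gate config lacks 'vertices'", call. = FALSE)
    verts <- if (is.matrix(cfg$vertices)) cfg$vertices else
      do.call(rbind, lapply(cfg$vertices, function(v) as.numeric(unlist(v))))
  }
  gate(name = cfg$name, kind = kind, channels = as.character(unlist(cfg$channels)),
       lo = cfg$lo, hi = cfg$hi, at = cfg$at,
       side = if (is.null(cfg$side)) "above" else cfg$side,
       xlim = as.numeric(unlist(cfg$xlim)), ylim = as.numeric(unlist(cfg$ylim)),
       vertices = verts, x_at = cfg$x_at, y_at = cfg$y_at,
       transform = cfg$transform)
}

#' Parse a gating strategy from a config file or list
#'
#' The config schema (YAML or JSON, `version: 1`) declares the `root`
#' population, an optional `denominator`, and a list of `gates`, each with a
#' `parent`, the gate fields of [gate()], and `child`/`children` names. The
#' parser rejects cyclic or duplicate definitions and children referencing an
#' unknown parent.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` file, or an equivalent list.
#' @return A [gating_strategy()].
#' @export
parse_gating_strategy <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("file not found: %s", x), call. = FALSE)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(x)
    }
  }
  stopifnot(is.list(x))
  if (is.null(x$root)) stop("strategy config lacks 'root'", call. = FALSE)
  entries <- lapply(x$gates, function(gc) {
    if (is.null(gc$parent)) stop(sprintf("gate '%s' lacks a parent", gc$name), call. = FALSE)
    list(parent = gc$parent, gate = gate_from_config(gc),
         child = gc$child,
         children = if (!is.null(gc$children)) as.character(unlist(gc$children)))
  })
  gating_strategy(root = x$root, entries = entries,
                  denominator = if (is.null(x$denominator)) x$root else x$denominator)
}

#' Serialize a gating strategy to YAML
#'
#' @param strategy A [gating_strategy()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_gating_strategy <- function(strategy, path) {
  stopifnot(inherits(strategy, "gating_strategy"))
  cfg <- list(version = 1L, root = strategy$root,
              denominator = strategy$denominator,
              gates = lapply(strategy$entries, function(e) {
                gc <- gate_to_config(e$gate)
                gc$parent <- e$parent
                if (e$gate$kind == "quadrant") gc$children <- as.list(e$children)
                else gc$child <- e$children
                gc
              }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
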