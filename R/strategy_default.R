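#' Canonical T cell:monocyte complex gating strategy
#'
#' Builds the hierarchical strategy used throughout this package to detect
#' T cell:monocyte complexes and their subsets in PBMC acquisitions:
#'
#' 1. `live` — viability-dye-low events (threshold, arcsinh scale);
#' 2. `singlet` — a proportional FSC_H-vs-FSC_A band (triangular polygon
#'    through the origin), the conventional pulse-geometry singlet gate that
#'    tightly bound complexes survive;
#' 3. CD3 x CD14 quadrant — `CD3posCD14pos` (complex candidates), `T`
#'    (CD3+CD14-), `M` (CD3-CD14+ monocytes), `nonTM`;
#' 4. within `CD3posCD14pos`, a CD14 threshold separates `complexes`
#'    (CD14hi: intact T cell:monocyte pairs at full monocyte CD14) from
#'    `debrisT` (CD14mid: single T cells carrying monocyte debris);
#' 5. within `complexes` and within `T`, CD4 x CD8 quadrants
#'    (`CD4*`, `CD8*`, `DPOS*`, `DNEG*`) and CD45RA x CCR7 quadrants
#'    (`naive*`, `Tcm*`, `Tem*`, `Temra*`).
#'
#' Fluorescence geometry is interpreted on the arcsinh scale (cofactor 150);
#' scatter on the linear scale. The default cut positions are calibrated to
#' the default simulator marker models and are all exposed as arguments —
#' real acquisitions require user calibration. The CD14 hi/mid split defaults
#' to the arcsinh midpoint between the debris-bound CD14 level and the
#' monocyte CD14 level.
#'
#' @param cofactor Arcsinh cofactor for fluorescence channels.
#' @param viability_cut Raw-unit viability cut; events below are live.
#' @param singlet_band `c(lo, hi)` bounds of FSC_H / FSC_A for singlets.
#' @param scatter_max Upper bound of the scatter range covered by the singlet
#'   polygon.
#' @param cd3_cut,cd14_cut,cd4_cut,cd8_cut,cd45ra_cut,ccr7_cut Raw-unit
#'   positivity cuts for the marker quadrants.
#' @param cd14_split Raw-unit CD14hi/CD14mid split; `NULL` uses the midpoint
#'   (on the arcsinh scale) between `cd14_debris_level * 1000` and 1000, the
#'   default simulator levels.
#' @param cd14_debris_level Debris-bound CD14 level (fraction of monocyte
#'   CD14) used for the default split.
#' @param cd45_pregate If `TRUE`, insert a CD45-vs-SSC rectangle gate between
#'   `live` and `singlet` (the conventional clean-up gate; complex frequency
#'   should be essentially unaffected by it).
#' @param cd45_cut Raw-unit CD45 positivity cut for the pre-gate.
#' @return A [gating_strategy()] with denominator `singlet`.
#' @export
#' @examples
#' strat <- tm_strategy()
#' strat$populations
tm_strategy <- function(cofactor = 150, viability_cut = 200,
                        singlet_band = c(0.75, 1.15), scatter_max = 1e7,
                        cd3_cut = 100, cd14_cut = 60, cd14_split = NULL,
                        cd14_debris_level = 0.15,
                        cd4_cut = 100, cd8_cut = 100,
                        cd45ra_cut = 100, ccr7_cut = 100,
                        cd45_pregate = FALSE, cd45_cut = 500) {
  tf <- function(x) asinh(x / cofactor)
  fluor <- list(type = "asinh", cofactor = cofactor)
  if (is.null(cd14_split)) {
    cd14_split <- cofactor * sinh((tf(cd14_debris_level * 1000) + tf(1000)) / 2)
  }
  entries <- list(
    list(parent = "all", child = "live",
         gate = gate("live_gate", "threshold", "viability",
                     at = tf(viability_cut), side = "below", transform = fluor))
  )
  singlet_parent <- "live"
  if (cd45_pregate) {
    entries <- c(entries, list(
      list(parent = "live", child = "cd45pos",
           gate = gate("cd45_ssc", "rectangle", c("CD45", "SSC_A"),
                       xlim = c(tf(cd45_cut), Inf), ylim = c(0, scatter_max),
                       transform = list(CD45 = fluor, SSC_A = "identity")))))
    singlet_parent <- "cd45pos"
  }
  singlet_poly <- rbind(c(0, 0),
                        c(scatter_max, singlet_band[1] * scatter_max),
                        c(scatter_max, singlet_band[2] * scatter_max))
  entries <- c(entries, list(
    list(parent = singlet_parent, child = "singlet",
         gate = gate("singlet_gate", "polygon", c("FSC_A", "FSC_H"),
                     vertices = singlet_poly)),
    list(parent = "singlet",
         children = c("CD3posCD14pos", "T", "M", "nonTM"),
         gate = gate("cd3_cd14", "quadrant", c("CD3", "CD14"),
                     x_at = tf(cd3_cut), y_at = tf(cd14_cut), transform = fluor)),
    list(parent = "CD3posCD14pos", child = "complexes",
         gate = gate("cd14_hi", "threshold", "CD14",
                     at = tf(cd14_split), side = "above", transform = fluor)),
    list(parent = "CD3posCD14pos", child = "debrisT",
         gate = gate("cd14_mid", "threshold", "CD14",
                     at = tf(cd14_split), side = "below", transform = fluor))
  ))
  subset_quads <- function(parent, suffix) {
    list(
      list(parent = parent,
           children = paste0(c("DPOS", "CD4", "CD8", "DNEG"), suffix),
           gate = gate(paste0("cd4_cd8_", suffix), "quadrant", c("CD4", "CD8"),
                       x_at = tf(cd4_cut), y_at = tf(cd8_cut), transform = fluor)),
      list(parent = parent,
           children = paste0(c("naive", "Temra", "Tcm", "Tem"), suffix),
           gate = gate(paste0("mem_", suffix), "quadrant", c("CD45RA", "CCR7"),
                       x_at = tf(cd45ra_cut), y_at = tf(ccr7_cut), transform = fluor))
    )
  }
  entries <- c(entries, subset_quads("complexes", "complex"), subset_quads("T", "T"))
  gating_strategy(root = "all", entries = entries, denominator = "singlet")
}
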