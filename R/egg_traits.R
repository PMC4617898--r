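#' Egg shell shape index
#'
#' Ratio of the egg's short length to the cube root of its weight. Two
#' variants are provided. The `"table"` variant, `SLE / (10 * EW^(1/3))`,
#' reproduces the conventional summary-table value (about 1.1 for a 61 g
#' egg with a 43 mm short length) and is the default. The `"printed"`
#' variant, `(SLE/10) / (EW/10)^(1/3)`, follows the formula as commonly
#' typeset; it differs by a factor of `10^(2/3)`.
#'
#' @param short_length_mm short length of the egg (SLE), mm.
#' @param egg_weight_g egg weight (EW), g; must be positive.
#' @param variant `"table"` (default) or `"printed"`.
#' @return numeric shape index (dimension-inconsistent units by construction).
#' @examples
#' egg_shape_index(43.37, 61.11) # about 1.10
#' @export
egg_shape_index <- function(short_length_mm, egg_weight_g,
                            variant = c("table", "printed")) {
  variant <- match.arg(variant)
  stopifnot(all(egg_weight_g > 0))
  switch(variant,
         table = short_length_mm / (10 * egg_weight_g^(1 / 3)),
         printed = (short_length_mm / 10) / (egg_weight_g / 10)^(1 / 3))
}

#' Egg shell colour index from chromameter readings
#'
#' Combines lightness L*, redness a* and yellowness b* into a single shell
#' colour score. The `"printed"` variant is `100 - (L* - a* - b*)` (default);
#' the `"table"` variant is `L* - a* - b*`, which matches typical summary
#' statistics of around 25 for a brown egg. The two are complementary
#' (they sum to 100).
#'
#' @param L,a,b chromameter lightness, redness, yellowness.
#' @param variant `"printed"` (default) or `"table"`.
#' @export
egg_shell_colour <- function(L, a, b, variant = c("printed", "table")) {
  variant <- match.arg(variant)
  esc <- L - a - b
  if (variant == "printed") 100 - esc else esc
}

#' Haugh unit
#'
#' Albumen-quality index `100 * log10(H - 1.7 * EW^0.37 + 7.57)` where `H`
#' is the albumen height (mm) and `EW` the egg weight (g). Base-10
#' logarithm, the standard Haugh definition.
#'
#' @param albumen_height_mm albumen height H, mm.
#' @param egg_weight_g egg weight, g.
#' @return Haugh units. Errors if the log argument is non-positive,
#'   naming the offending record index.
#' @examples
#' haugh_unit(6, 60) # about 76.6
#' @export
haugh_unit <- function(albumen_height_mm, egg_weight_g) {
  arg <- albumen_height_mm - 1.7 * egg_weight_g^0.37 + 7.57
  bad <- which(arg <= 0)
  if (length(bad))
    stop("Haugh unit log argument non-positive for record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  100 * log10(arg)
}

#' Yolk index
#'
#' Yolk weight divided by egg weight.
#' @param yolk_weight_g,egg_weight_g weights in grams.
#' @export
yolk_index <- function(yolk_weight_g, egg_weight_g) {
  stopifnot(all(egg_weight_g > 0))
  yolk_weight_g / egg_weight_g
}

#' All derived egg-quality indices for one egg
#'
#' Convenience wrapper returning the four derived traits from the raw
#' measurements of a single egg (or vectors over eggs).
#'
#' @inheritParams egg_shape_index
#' @inheritParams egg_shell_colour
#' @inheritParams haugh_unit
#' @inheritParams yolk_index
#' @param esshape_variant,esc_variant variant switches passed through.
#' @return data.frame with columns `ESshape`, `ESC`, `HU`, `YOLKIND`.
#' @export
compute_derived_traits <- function(short_length_mm, egg_weight_g, L, a, b,
                                   albumen_height_mm, yolk_weight_g,
                                   esshape_variant = "table",
                                   esc_variant = "printed") {
  data.frame(
    ESshape = egg_shape_index(short_length_mm, egg_weight_g, esshape_variant),
    ESC = egg_shell_colour(L, a, b, esc_variant),
    HU = haugh_unit(albumen_height_mm, egg_weight_g),
    YOLKIND = yolk_index(yolk_weight_g, egg_weight_g)
  )
}

# Laying-period windows in weeks of age, closed intervals.
epr_windows <- function() {
  list(EPR = c(18L, 75L), EPR1 = c(18L, 30L), EPR2 = c(31L, 49L),
       EPR3 = c(50L, 75L))
}

#' Egg production rate over a laying period
#'
#' Percentage of eggs per hen-day for one cage, restricted to a standard
#' laying period: global production weeks 18-75 (`EPR`), increasing phase
#' 18-30 (`EPR1`), plateau 31-49 (`EPR2`), persistence 50-75 (`EPR3`).
#' Week boundaries are closed (inclusive).
#'
#' @param eggs integer vector, eggs collected per ledger entry.
#' @param hen_days hen-days at risk per ledger entry (positive).
#' @param week week of age of each ledger entry, within 18-75.
#' @param period one of `"EPR"`, `"EPR1"`, `"EPR2"`, `"EPR3"`.
#' @return egg production rate, percent.
#' @examples
#' compute_epr(eggs = 84, hen_days = 84, week = 20, period = "EPR1") # 100
#' @export
compute_epr <- function(eggs, hen_days, week,
                        period = c("EPR", "EPR1", "EPR2", "EPR3")) {
  period <- match.arg(period)
  stopifnot(length(eggs) == length(hen_days), length(eggs) == length(week),
            all(hen_days > 0), all(eggs >= 0))
  if (any(week < 18 | week > 75))
    stop("ledger weeks outside the laying window 18-75")
  w <- epr_windows()[[period]]
  keep <- week >= w[1] & week <= w[2]
  if (!any(keep)) return(NA_real_)
  100 * sum(eggs[keep]) / sum(hen_days[keep])
}
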