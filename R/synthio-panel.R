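## Curated wine-volatile panel: name, polar-column RI, main EI fragments,
## typical wine concentration (ug/L) and literature odor threshold (ug/L).
## Fragments are the handful of diagnostic ions a unit-mass quadrupole sees.
wine_volatile_table <- function() {
  sp <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("mz", "intensity")))
  list(
    list("Isoamyl acetate",      1122, sp(43,999, 70,620, 55,450, 87,210, 61,120), 450,  30),
    list("Ethyl hexanoate",      1233, sp(88,999, 99,700, 60,340, 101,300, 115,150), 300, 14),
    list("Ethyl heptanoate",     1331, sp(88,999, 101,600, 113,340, 141,160), 400, 220),
    list("Methyl octanoate",     1385, sp(74,999, 87,720, 127,300, 158,60), 1.5, 200),
    list("Ethyl octanoate",      1435, sp(88,999, 101,750, 127,400, 57,310, 172,80), 45, 5),
    list("Isoamyl hexanoate",    1450, sp(70,999, 43,880, 99,650, 117,300), 1.6, 1000),
    list("Ethyl nonanoate",      1530, sp(88,999, 101,680, 141,300, 155,90), 1.0, 1300),
    list("Linalool",             1547, sp(71,999, 93,870, 55,600, 121,400, 80,300, 136,130), 11, 25.2),
    list("1-Hexanol",            1355, sp(56,999, 43,720, 69,360, 84,160), 1800, 8000),
    list("1-Octanol",            1559, sp(56,999, 55,830, 70,610, 84,400, 41,350), 15, 110),
    list("Caryophyllene",        1595, sp(93,999, 133,820, 91,700, 189,420, 204,160), 4, 64),
    list("1-Nonanol",            1660, sp(56,999, 70,700, 55,640, 98,310), 13, 600),
    list("alpha-Terpineol",      1697, sp(59,999, 93,710, 121,520, 136,260), 9, 250),
    list("TDN",                  1734, sp(157,999, 142,800, 115,320, 172,260), 6, 2),
    list("Methyl salicylate",    1770, sp(120,999, 152,620, 92,360, 121,180), 12, 40),
    list("2-Phenylethyl acetate",1813, sp(104,999, 43,560, 91,360, 105,210), 35, 250),
    list("beta-Damascenone",     1820, sp(69,999, 121,850, 190,520, 105,410, 91,260), 8.59, 4.5),
    list("Ethyl hydrocinnamate", 1885, sp(104,999, 178,460, 107,410, 91,310), 2.5, 1.6),
    list("beta-Ionone",          1940, sp(177,999, 192,420, 43,360, 135,220), 1.2, 0.09),
    list("1-Dodecanol",          1970, sp(55,999, 69,820, 83,620, 97,410, 111,210), 0.4, 1000),
    list("Ethyl tetradecenoate", 2090, sp(88,999, 101,760, 55,420, 236,90), 50, NA),
    list("Ethyl hexadecanoate",  2250, sp(88,999, 101,810, 157,260, 284,110), 200, 1500),
    list("p-Cymene",             1270, sp(119,999, 134,460, 91,310, 117,160), 3, 11.4),
    list("Terpinolene",          1282, sp(121,999, 136,720, 93,660, 79,300), 2, 200)
  )
}

#' Internal-standard specifications
#'
#' The three spiked internal standards at their working concentrations:
#' 2-octanol 50 ug/L (response normaliser), 4-methyl-2-pentanol 100 ug/L and
#' 3-octanone 50 ug/L (quality control).
#' @return List of [compound_spec()] objects with `cv = 0`.
#' @export
internal_standard_specs <- function() {
  sp <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("mz", "intensity")))
  list(
    compound_spec("2-Octanol", sp(45,999, 97,420, 55,360, 111,80), true_ri = 1420,
                  base_conc = 50, cv = 0),
    compound_spec("4-Methyl-2-pentanol", sp(45,999, 69,520, 87,160), true_ri = 1170,
                  base_conc = 100, cv = 0),
    compound_spec("3-Octanone", sp(43,999, 99,760, 71,620, 128,160), true_ri = 1255,
                  base_conc = 50, cv = 0)
  )
}

#' Generate the synthetic wine-volatile compound panel
#'
#' Builds a panel of `n` compounds: the curated named wine volatiles first,
#' padded with procedurally generated "unknown" volatiles (random 4-8 fragment
#' spectra, RIs spread over the ladder range). The first `n_planted` curated
#' compounds receive a rootstock effect: the own-rooted level is shifted up or
#' down by `min_shift` to `min_shift + 0.15` relative to grafted vines. The
#' default 35-50% keeps the planted one-way ANOVA contrasts (6 vs 18
#' biological samples at 15% CV) comfortably powered, so recovery tests probe
#' the pipeline rather than marginal F-test power.
#'
#' @param n Panel size.
#' @param n_planted Number of compounds given a rootstock effect.
#' @param min_shift Minimum relative mean shift for planted compounds (0.35 =
#'   35%).
#' @param cv Biological coefficient of variation for every compound.
#' @param seed Seed for the procedural part (private RNG stream; does not
#'   disturb the caller's RNG state).
#' @return List of [compound_spec()] objects; planted compounds carry a
#'   non-empty `effect_multiplier`.
#' @export
synthetic_compound_panel <- function(n = 60, n_planted = 12, min_shift = 0.35,
                                     cv = 0.15, seed = 1103L) {
  with_local_seed(seed, {
    base <- wine_volatile_table()
    if (n_planted > length(base)) stopf("n_planted exceeds the curated panel")
    specs <- vector("list", n)
    used_ri <- vapply(base, `[[`, numeric(1), 2)
    for (i in seq_along(base)) {
      b <- base[[i]]
      eff <- numeric(0)
      if (i <= n_planted) {
        shift <- stats::runif(1, min_shift, min_shift + 0.15)
        up <- i %% 2 == 1
        eff <- c(Own = if (up) 1 + shift else 1 / (1 + shift))
      }
      specs[[i]] <- compound_spec(b[[1]], b[[3]], true_ri = b[[2]],
                                  base_conc = b[[4]], effect_multiplier = eff,
                                  cv = cv, odor_threshold = b[[5]])
    }
    n_extra <- n - length(base)
    if (n_extra > 0) {
      ri_pool <- seq(760, 2900, length.out = 4 * n_extra)
      ri_pool <- ri_pool[!vapply(ri_pool, function(r) any(abs(r - used_ri) < 18), logical(1))]
      ris <- sort(sample(ri_pool, n_extra))
      for (j in seq_len(n_extra)) {
        nfrag <- sample(4:8, 1)
        mzs <- sort(sample(29:250, nfrag))
        ints <- c(999, round(stats::runif(nfrag - 1, 60, 850)))
        specs[[length(base) + j]] <- compound_spec(
          sprintf("Unknown-%02d", j), cbind(mz = mzs, intensity = ints),
          true_ri = ris[j], base_conc = exp(stats::runif(1, log(0.5), log(300))),
          cv = cv)
        used_ri <- c(used_ri, ris[j])
      }
    }
    specs[seq_len(n)]
  })
}

#' Default synthetic study recipe
#'
#' The reference study the package's tests and examples use: 4 root systems x
#' 3 irrigation regimes x 2 vines, each injected twice (48 runs, 24 biological
#' samples); 60 compounds of which 12 carry a >= 25% rootstock shift at 15%
#' biological CV; the three internal standards; C7-C30 alkane ladder.
#'
#' @param seed Study seed (controls biological noise, drift and counting
#'   noise).
#' @param planted If `FALSE`, all effect multipliers are stripped (a null
#'   study).
#' @param cv Biological coefficient of variation.
#' @return A [study_recipe()].
#' @export
default_study_recipe <- function(seed = 1L, planted = TRUE, cv = 0.15) {
  compounds <- synthetic_compound_panel(n = 60, n_planted = if (planted) 12 else 0,
                                        cv = cv)
  study_recipe(design = study_design(), compounds = compounds,
               internal_standards = internal_standard_specs(), seed = seed)
}
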