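#' Describe a genome layout for simulation
#'
#' A genome layout names the chromosomes, their lengths and the target mean
#' probe spacing of the array design.  The default spacing of 1,200 bp
#' mirrors high-density whole-genome cattle CGH designs (~2.1M probes over a
#' ~2.6 Gb genome).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp
#'   (names are chromosome names).
#' @param probe_spacing_bp target mean distance between adjacent probes (bp).
#' @param sex_chromosome name of the sex chromosome present in single copy in
#'   male samples, or `NA` if none. Must be one of `names(chromosomes)` when
#'   not `NA`.
#'
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 5e6, chrX = 2e6), probe_spacing_bp = 1200,
#'               sex_chromosome = "chrX")
#' @export
genome_layout <- function(chromosomes,
                          probe_spacing_bp = 1200,
                          sex_chromosome = NA_character_) {
  if (length(chromosomes) == 0L || is.null(names(chromosomes)) ||
      any(!nzchar(names(chromosomes)))) {
    stop("`chromosomes` must be a named vector of lengths")
  }
  if (anyDuplicated(names(chromosomes))) {
    stop("chromosome names must be unique")
  }
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (!is.finite(probe_spacing_bp) || probe_spacing_bp <= 0) {
    stop("`probe_spacing_bp` must be positive")
  }
  if (!is.na(sex_chromosome) && !sex_chromosome %in% names(chromosomes)) {
    stop("`sex_chromosome` is not among the chromosome names")
  }
  structure(
    list(chromosomes = chromosomes,
         probe_spacing_bp = probe_spacing_bp,
         sex_chromosome = sex_chromosome),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", length(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes), big.mark = ","), "bp total\n")
  cat("  mean probe spacing:", x$probe_spacing_bp, "bp\n")
  if (!is.na(x$sex_chromosome)) {
    cat("  sex chromosome:", x$sex_chromosome, "\n")
  }
  invisible(x)
}

#' Per-probe noise model for simulated hybridisations
#'
#' Gaussian noise on the log2 scale: independent per-probe noise with
#' standard deviation `probe_sd`, plus one per-sample baseline shift drawn
#' with standard deviation `sample_shift_sd` (emulating residual dye/loading
#' differences that per-sample normalisation must remove).
#'
#' @param probe_sd per-probe standard deviation (log2 units), >= 0.
#' @param sample_shift_sd per-sample baseline shift SD (log2 units), >= 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(probe_sd = 0.15, sample_shift_sd = 0) {
  if (probe_sd < 0 || sample_shift_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  structure(list(probe_sd = probe_sd, sample_shift_sd = sample_shift_sd),
            class = "noise_model")
}

#' The default 41-trait catalogue
#'
#' Returns the standard dairy-cattle predicted-transmitting-ability (PTA)
#' trait catalogue used throughout the package: 6 production, 9
#' reproduction, 8 health and 18 body-conformation (type) traits.  The
#' `block` attribute records the category of each trait; trait simulation
#' uses these blocks for its residual correlation structure.
#'
#' @return data.frame with columns `trait` and `block`.
#' @export
trait_catalogue <- function() {
  production <- c("Milk", "Fat", "Protein", "Fat_Percent", "Pro_Percent",
                  "Net_Merit")
  reproduction <- c("Prod_Life", "Sire_Calv_Ease", "Dtr_Calv_Ease",
                    "Sire_Still_Birth", "Dtr_Still_Birth", "Dtr_Preg_Rate",
                    "Heifer_Conc_Rate", "Cow_Conc_Rate", "gestleng")
  health <- c("SCS", "CALC", "DSAB", "KETO", "MAST", "METR", "RETP",
              "livability")
  type <- c("Final_Score", "Stature", "Strength", "Dairy_Form", "Foot_Angle",
            "Rear_Legs_Side", "Body_Depth", "Rump_Angle", "Rump_Width",
            "Fore_Udder_Att", "Rear_Udder_Height", "Udder_Depth",
            "Udder_Cleft", "Front_Teat_Pla", "Teat_Length", "Rear_Legs_Rear",
            "Feet_And_Legs", "Rear_Teat_Pla")
  data.frame(
    trait = c(production, reproduction, health, type),
    block = rep(c("production", "reproduction", "health", "type"),
                times = c(length(production), length(reproduction),
                          length(health), length(type))),
    stringsAsFactors = FALSE
  )
}

#' Phenotype generation model
#'
#' Trait values are built as `sum(effect * (copy_number - 2))` over the
#' effect loci plus a correlated Gaussian residual.  Residuals are
#' block-correlated: traits within the same category share correlation
#' `within_block_cor`, traits in different categories `between_block_cor`.
#'
#' @param traits data.frame with columns `trait` and `block`
#'   (default [trait_catalogue()]).
#' @param dosage_effects data.frame with columns `locus_id`, `trait`,
#'   `effect` (trait units per copy deviation from the diploid baseline); may
#'   be empty.
#' @param residual_sd residual standard deviation, recycled across traits.
#' @param within_block_cor,between_block_cor residual correlations.
#' @return An object of class `phenotype_model`.
#' @export
phenotype_model <- function(traits = trait_catalogue(),
                            dosage_effects = NULL,
                            residual_sd = 1,
                            within_block_cor = 0.5,
                            between_block_cor = 0.05) {
  stopifnot(is.data.frame(traits), all(c("trait", "block") %in% names(traits)))
  if (anyDuplicated(traits$trait)) stop("trait names must be unique")
  if (is.null(dosage_effects)) {
    dosage_effects <- data.frame(locus_id = character(), trait = character(),
                                 effect = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("locus_id", "trait", "effect") %in% names(dosage_effects)))
  if (nrow(dosage_effects) && !all(dosage_effects$trait %in% traits$trait)) {
    stop("dosage effects refer to traits outside the catalogue")
  }
  if (any(residual_sd < 0)) stop("residual_sd must be >= 0")
  if (abs(within_block_cor) > 1 || abs(between_block_cor) > 1) {
    stop("correlations must be in [-1, 1]")
  }
  residual_sd <- rep_len(residual_sd, nrow(traits))
  structure(
    list(traits = traits, dosage_effects = dosage_effects,
         residual_sd = residual_sd,
         within_block_cor = within_block_cor,
         between_block_cor = between_block_cor),
    class = "phenotype_model"
  )
}

# Deterministic seed-splitting: every simulator derives the sub-seed for each
# independent random draw from the user seed and a stage label, so stages can
# be re-run in isolation yet reproduce the run_all() output exactly.
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}
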