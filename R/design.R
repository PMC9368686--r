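#' Sampling design of the adulteration experiment
#'
#' Defaults reproduce the study design this package emulates: 24 pure mutton
#' samples, 24 essence-treated pork samples (8 per pork part: front leg, hind
#' leg, back), and 144 adulterated mixtures (8 replicates x 6 proportions x 3
#' parts), 192 samples in total, each later represented by 10 block-mean
#' spectra.
#'
#' @param n_mutton number of pure mutton samples.
#' @param n_pork_per_part pure pork samples per part.
#' @param parts pork part labels.
#' @param proportions pork mass fractions (g/g) of the mixtures, each in
#'   (0, 1).
#' @param replicates_per_cell mixture replicates per proportion x part cell.
#' @param blocks_per_sample block-mean spectra extracted per sample.
#' @param seed integer seed stored with the design.
#' @return object of class `sample_design`.
#' @export
sample_design <- function(n_mutton = 24L, n_pork_per_part = 8L,
                          parts = c("front_leg", "hind_leg", "back"),
                          proportions = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40),
                          replicates_per_cell = 8L,
                          blocks_per_sample = 10L, seed = 1L) {
  check_number(n_mutton, "n_mutton", 1)
  check_number(n_pork_per_part, "n_pork_per_part", 1)
  check_number(replicates_per_cell, "replicates_per_cell", 1)
  check_number(blocks_per_sample, "blocks_per_sample", 1)
  if (length(parts) < 1L) stop_nirmeat("sample_design: need >= 1 part")
  if (any(proportions <= 0) || any(proportions >= 1)) {
    stop_nirmeat("sample_design: proportions must lie in (0, 1)")
  }
  structure(list(n_mutton = as.integer(n_mutton),
                 n_pork_per_part = as.integer(n_pork_per_part),
                 parts = as.character(parts),
                 proportions = as.numeric(proportions),
                 replicates_per_cell = as.integer(replicates_per_cell),
                 blocks_per_sample = as.integer(blocks_per_sample),
                 seed = as.integer(seed)),
            class = "sample_design")
}

#' Expand a design into its sample table
#'
#' Pure function of the design: one row per physical sample with id, class
#' (`M` mutton, `P` pork, `MP` mixture), pork part and pork mass fraction
#' (0 for pure mutton, 1 for pure pork).
#'
#' @param design a [sample_design()].
#' @return `data.frame` with columns `sample_id`, `class`, `part`,
#'   `proportion`; the design is attached as attribute `design`.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "sample_design"))
  m <- data.frame(class = "M", part = "none", proportion = 0,
                  stringsAsFactors = FALSE)[rep(1L, design$n_mutton), ]
  p <- expand.grid(rep = seq_len(design$n_pork_per_part),
                   part = design$parts, stringsAsFactors = FALSE)
  p <- data.frame(class = "P", part = p$part, proportion = 1,
                  stringsAsFactors = FALSE)
  mp <- expand.grid(rep = seq_len(design$replicates_per_cell),
                    proportion = design$proportions,
                    part = design$parts, stringsAsFactors = FALSE)
  mp <- data.frame(class = "MP", part = mp$part, proportion = mp$proportion,
                   stringsAsFactors = FALSE)
  tab <- rbind(m, p, mp)
  tab$sample_id <- sprintf("%s%03d", tab$class,
                           stats::ave(seq_len(nrow(tab)), tab$class,
                                      FUN = seq_along))
  tab <- tab[, c("sample_id", "class", "part", "proportion")]
  rownames(tab) <- NULL
  n_mp <- design$replicates_per_cell * length(design$proportions) *
    length(design$parts)
  stopifnot(sum(tab$class == "MP") == n_mp)
  attr(tab, "design") <- design
  tab
}
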