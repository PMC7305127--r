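#' Sample design for a two-genotype pulldown experiment
#'
#' Describes the columns of a site or protein-group table: one row per
#' sample, with its genotype (biotin-ligase knock-in or wild-type control)
#' and optional tissue / age annotations.
#'
#' @param sample character vector of unique sample names, in table column
#'   order.
#' @param genotype character vector, each `"knockin"` or `"wildtype"`.
#' @param tissue optional character vector (e.g. `"heart"`, `"quadriceps"`).
#' @param age optional character vector (e.g. `"adult"`, `"neonatal"`).
#' @return a `sample_design` data.frame.
#' @examples
#' sample_design(c("ki1", "ki2", "wt1", "wt2"),
#'               c("knockin", "knockin", "wildtype", "wildtype"))
#' @export
sample_design <- function(sample, genotype, tissue = NULL, age = NULL) {
  sample <- as.character(sample)
  genotype <- as.character(genotype)
  if (length(sample) != length(genotype)) {
    stop_input("sample and genotype must have equal length")
  }
  if (anyDuplicated(sample)) stop_input("sample names must be unique")
  bad <- setdiff(unique(genotype), c("knockin", "wildtype"))
  if (length(bad)) {
    stop_input("genotype must be 'knockin' or 'wildtype', got: %s",
               paste(bad, collapse = ", "))
  }
  design <- data.frame(sample = sample, genotype = genotype,
                       stringsAsFactors = FALSE)
  if (!is.null(tissue)) design$tissue <- as.character(tissue)
  if (!is.null(age)) design$age <- as.character(age)
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Validate that a design carries both genotypes
#' @noRd
check_two_genotypes <- function(design) {
  for (g in c("knockin", "wildtype")) {
    if (!any(design$genotype == g)) {
      stop_input("design has no '%s' samples", g)
    }
  }
  invisible(design)
}

design_samples <- function(design, genotype = NULL) {
  if (is.null(genotype)) design$sample else design$sample[design$genotype == genotype]
}
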