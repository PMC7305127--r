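#' Biotinylation-site table
#'
#' One row per (protein, residue) biotinylation site with one intensity
#' column per sample of the design. Intensity 0 encodes a missing value
#' (MaxQuant convention). Optional columns `segment_label` / `segment_kind`
#' are added by [annotate_sites()].
#'
#' @param records data.frame with columns `protein_id`, `position`, one
#'   numeric column per design sample, and optionally `localization_prob`.
#' @param design a [sample_design()].
#' @return a `site_table` data.frame with the design stored as an attribute.
#' @export
site_table <- function(records, design) {
  stopifnot(inherits(design, "sample_design"))
  required <- c("protein_id", "position")
  missing_cols <- setdiff(c(required, design$sample), names(records))
  if (length(missing_cols)) {
    stop_input("records lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records$protein_id <- as.character(records$protein_id)
  records$position <- as.integer(records$position)
  if (nrow(records) && any(records$position < 1L)) {
    stop_input("positions must be >= 1")
  }
  for (s in design$sample) {
    v <- records[[s]]
    if (!is.numeric(v)) stop_input("intensity column '%s' is not numeric", s)
    if (length(v) && any(v < 0, na.rm = TRUE)) {
      stop_input("negative intensity in column '%s'", s)
    }
    v[is.na(v)] <- 0
    records[[s]] <- as.numeric(v)
  }
  key <- paste(records$protein_id, records$position)
  if (anyDuplicated(key)) stop_input("duplicate (protein_id, position) records")
  structure(records, design = design,
            class = c("site_table", "data.frame"))
}

#' @export
print.site_table <- function(x, ...) {
  d <- site_design(x)
  cat(sprintf("Biotinylation-site table: %d sites, %d knock-in + %d wild-type samples\n",
              nrow(x), sum(d$genotype == "knockin"), sum(d$genotype == "wildtype")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Design of a site or protein-group table
#' @param x a `site_table` or `proteingroup_table`.
#' @return the [sample_design()] the table was built with.
#' @export
site_design <- function(x) attr(x, "design")

intensity_matrix <- function(table, samples = NULL) {
  design <- site_design(table)
  samples <- samples %||% design$sample
  as.matrix(as.data.frame(table)[, samples, drop = FALSE])
}

restore_site_table <- function(records, design) {
  structure(records, design = design, class = c("site_table", "data.frame"))
}

maxquant_dropped_rows <- function(df, id_col) {
  ids <- as.character(df[[id_col]])
  drop <- startsWith(ids, "REV__") | startsWith(ids, "CON__")
  for (marker in c("Reverse", "Potential.contaminant", "Potential contaminant",
                   "Only.identified.by.site", "Only identified by site")) {
    if (marker %in% names(df)) drop <- drop | df[[marker]] %in% "+"
  }
  drop
}

#' Read a MaxQuant-style biotinylation-site table
#'
#' Parses a tab-separated sites file ("biotinSites" dialect). Accepted id
#' columns are `protein_id`, `Proteins` or `Protein`; positions come from
#' `position` or `Position`; intensities from `"Intensity <sample>"` or bare
#' `<sample>` columns. Rows flagged as reverse-database hits or contaminants
#' (id prefix `REV__`/`CON__`, or a `+` in a marker column) are dropped.
#'
#' @param path path to the tab-separated file.
#' @param design a [sample_design()]; every sample must have an intensity
#'   column in the file.
#' @return a [site_table()].
#' @export
read_site_table <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- intersect(c("protein_id", "Proteins", "Protein"), names(df))[1L]
  pos_col <- intersect(c("position", "Position"), names(df))[1L]
  if (is.na(id_col)) stop_input("%s: no protein id column found", path)
  if (is.na(pos_col)) stop_input("%s: no position column found", path)
  int_cols <- character(length(design$sample))
  for (i in seq_along(design$sample)) {
    s <- design$sample[i]
    cand <- intersect(c(paste("Intensity", s), s), names(df))
    if (length(cand) == 0L) {
      stop_input("%s: missing intensity column for sample '%s'", path, s)
    }
    int_cols[i] <- cand[1L]
  }
  df <- df[!maxquant_dropped_rows(df, id_col), , drop = FALSE]
  records <- data.frame(protein_id = as.character(df[[id_col]]),
                        position = df[[pos_col]],
                        stringsAsFactors = FALSE)
  for (i in seq_along(design$sample)) {
    v <- df[[int_cols[i]]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop_input("%s: non-numeric intensity in column '%s', data row %d",
                   path, int_cols[i], bad[1L])
      }
      v <- num
    }
    v[is.na(v)] <- 0
    if (any(v < 0)) {
      stop_input("%s: negative intensity in column '%s', data row %d",
                 path, int_cols[i], which(v < 0)[1L])
    }
    records[[design$sample[i]]] <- v
  }
  lp_col <- intersect(c("localization_prob", "Localization prob"), names(df))[1L]
  if (!is.na(lp_col)) records$localization_prob <- df[[lp_col]]
  rownames(records) <- NULL
  site_table(records, design)
}

#' Write a site table as tab-separated text
#'
#' Columns are written in the MaxQuant-like dialect read back by
#' [read_site_table()] (`Proteins`, `Position`, `Intensity <sample>`).
#'
#' @param table a [site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  design <- site_design(table)
  df <- as.data.frame(table)
  out <- data.frame(Proteins = df$protein_id, Position = df$position,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in design$sample) out[[paste("Intensity", s)]] <- df[[s]]
  if ("localization_prob" %in% names(df)) {
    out[["Localization prob"]] <- df$localization_prob
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count valid values (intensity > 0) per genotype group
#' @noRd
valid_counts <- function(table, genotype) {
  m <- intensity_matrix(table, design_samples(site_design(table), genotype))
  if (nrow(m) == 0L) return(integer(0))
  rowSums(m > 0)
}

#' Parameters of the knock-in-specificity site filter
#'
#' Defaults follow the rule used to call ligase-specific sites: at least
#' three valid values (intensity > 0) in the knock-in group and at least two
#' more valid values than in the corresponding wild-type group.
#'
#' @param min_valid_knockin minimum number of valid knock-in values.
#' @param min_excess_over_wildtype minimum excess of knock-in over wild-type
#'   valid counts.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_valid_knockin = 3L, min_excess_over_wildtype = 2L) {
  if (min_valid_knockin < 0 || min_excess_over_wildtype < 0) {
    stop_input("filter parameters must be >= 0")
  }
  structure(list(min_valid_knockin = as.integer(min_valid_knockin),
                 min_excess_over_wildtype = as.integer(min_excess_over_wildtype)),
            class = "filter_params")
}

#' Keep knock-in-specific biotinylation sites
#'
#' Retains the records with `valid_knockin >= min_valid_knockin` and
#' `valid_knockin >= valid_wildtype + min_excess_over_wildtype`, where valid
#' means intensity > 0. Record order is preserved.
#'
#' @param table a [site_table()] whose design has both genotypes.
#' @param params a [filter_params()].
#' @return the filtered [site_table()].
#' @examples
#' d <- sample_design(c("k1","k2","k3","k4","w1","w2","w3","w4"),
#'                    rep(c("knockin","wildtype"), each = 4))
#' tb <- site_table(data.frame(protein_id = "P1", position = 10,
#'   k1 = 5, k2 = 3, k3 = 2, k4 = 0, w1 = 0, w2 = 0, w3 = 1, w4 = 0), d)
#' nrow(filter_specific_sites(tb))  # kept: 3 valid vs 1
#' @export
filter_specific_sites <- function(table, params = filter_params()) {
  design <- check_two_genotypes(site_design(table))
  ki <- valid_counts(table, "knockin")
  wt <- valid_counts(table, "wildtype")
  keep <- ki >= params$min_valid_knockin &
    ki >= wt + params$min_excess_over_wildtype
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  restore_site_table(out, design)
}

#' Annotate sites with their enclosing domain segment
#'
#' Adds `segment_label` and `segment_kind` columns, assigning each site the
#' segment whose closed interval `[start, end]` contains its position.
#'
#' @param table a [site_table()] for a single protein.
#' @param annotation a [domain_annotation()] for that protein.
#' @return the annotated [site_table()].
#' @export
annotate_sites <- function(table, annotation) {
  design <- site_design(table)
  df <- as.data.frame(table)
  if (nrow(df)) {
    mism <- df$protein_id != annotation_protein(annotation)
    if (any(mism)) {
      stop_input("record %d (protein '%s') does not match annotation protein '%s'",
                 which(mism)[1L], df$protein_id[which(mism)[1L]],
                 annotation_protein(annotation))
    }
    over <- df$position > annotation_length(annotation)
    if (any(over)) {
      stop_input("record %d: position %d beyond protein length %d",
                 which(over)[1L], df$position[which(over)[1L]],
                 annotation_length(annotation))
    }
    seg <- segment_at(annotation, df$position)
    df$segment_label <- seg$label
    df$segment_kind <- seg$kind
  } else {
    df$segment_label <- character(0)
    df$segment_kind <- character(0)
  }
  restore_site_table(df, design)
}
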