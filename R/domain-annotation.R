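#' Protein domain annotation
#'
#' An ordered, contiguous segmentation of a protein into folded domains and
#' unstructured regions, used by the contour-length geometry model. Segments
#' are 1-based, closed intervals that together cover `1..length` without
#' gaps or overlap.
#'
#' @param protein_id protein identifier the annotation refers to.
#' @param segments data.frame with columns `start`, `end` (1-based
#'   inclusive), `kind` (`"folded_domain"` or `"unstructured"`) and `label`
#'   (e.g. `"Ig7"`, `"Z-repeat region"`).
#' @return a `domain_annotation` data.frame with attributes `protein_id`
#'   and `length`.
#' @examples
#' domain_annotation("TTN_SIM", data.frame(
#'   start = c(1, 101, 190),
#'   end   = c(100, 189, 400),
#'   kind  = c("unstructured", "folded_domain", "unstructured"),
#'   label = c("linker1", "Ig1", "linker2")))
#' @export
domain_annotation <- function(protein_id, segments) {
  required <- c("start", "end", "kind", "label")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols)) {
    stop_input("segments lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  segments <- segments[order(segments$start), required, drop = FALSE]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$kind <- as.character(segments$kind)
  segments$label <- as.character(segments$label)
  bad_kind <- setdiff(unique(segments$kind), c("folded_domain", "unstructured"))
  if (length(bad_kind)) {
    stop_input("unknown segment kind(s): %s", paste(bad_kind, collapse = ", "))
  }
  if (any(segments$end < segments$start)) stop_input("segment end < start")
  if (segments$start[1L] != 1L) stop_input("segments must start at residue 1")
  n <- nrow(segments)
  if (n > 1L && any(segments$start[-1L] != segments$end[-n] + 1L)) {
    stop_input("segments must be contiguous and non-overlapping")
  }
  structure(segments,
            protein_id = as.character(protein_id),
            length = segments$end[n],
            class = c("domain_annotation", "data.frame"))
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("Domain annotation for %s (%d residues, %d segments)\n",
              attr(x, "protein_id"), attr(x, "length"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

annotation_length <- function(annotation) attr(annotation, "length")

annotation_protein <- function(annotation) attr(annotation, "protein_id")

#' Segment index containing each residue position
#' @noRd
segment_index_at <- function(annotation, position) {
  len <- annotation_length(annotation)
  if (any(position < 1L | position > len)) {
    stop_input("residue position out of range 1..%d", len)
  }
  findInterval(position, annotation$start)
}

#' Segment label and kind at residue positions
#'
#' @param annotation a [domain_annotation()].
#' @param position integer vector of 1-based residue positions.
#' @return data.frame with columns `label` and `kind`.
#' @export
segment_at <- function(annotation, position) {
  i <- segment_index_at(annotation, position)
  data.frame(label = annotation$label[i], kind = annotation$kind[i],
             stringsAsFactors = FALSE)
}

#' Read a domain annotation from a tab-separated file
#'
#' Expects columns `protein_id`, `start`, `end`, `kind`, `label`; one
#' protein per file.
#'
#' @param path file path.
#' @return a [domain_annotation()].
#' @export
read_domain_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df)) stop_input("annotation file lacks protein_id column")
  pid <- unique(df$protein_id)
  if (length(pid) != 1L) stop_input("annotation file must describe exactly one protein")
  domain_annotation(pid, df[c("start", "end", "kind", "label")])
}

#' Write a domain annotation to a tab-separated file
#'
#' @param annotation a [domain_annotation()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_domain_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df <- cbind(protein_id = annotation_protein(annotation), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
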