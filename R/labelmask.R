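#' Tissue label codes
#'
#' Integer codes used for the six head tissue classes throughout the
#' package: air 0, soft (non-brain) tissue 1, bone 2, grey matter 3, white
#' matter 4, CSF 5.
#' @return named integer vector.
#' @export
tissue_codes <- function() {
  c(air = 0L, soft = 1L, bone = 2L, gm = 3L, wm = 4L, csf = 5L)
}

#' Construct a label mask
#'
#' @param labels integer 3-D array of label codes.
#' @param table named integer vector mapping tissue name to code; must cover
#'   every code present in `labels`.
#' @param spacing,origin grid geometry (mm), as for [volume()].
#' @return object of class `suteac_labels`.
#' @export
label_mask <- function(labels, table = tissue_codes(),
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels))) stop("labels must not contain NA")
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% table))
    stop("label_table does not cover codes: ",
         paste(setdiff(present, table), collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(labels = labels, table = table, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "suteac_labels")
}

is_labels <- function(x) inherits(x, "suteac_labels")

#' @export
print.suteac_labels <- function(x, ...) {
  counts <- table(factor(as.vector(x$labels), levels = x$table,
                         labels = names(x$table)))
  cat(sprintf("suteac_labels: %s\n", paste(dim(x$labels), collapse = "x")))
  print(counts)
  invisible(x)
}

#' Binary mask of one tissue class
#' @param lm a `suteac_labels`.
#' @param class tissue name present in the label table.
#' @return logical 3-D array.
#' @export
class_mask <- function(lm, class) {
  stopifnot(is_labels(lm))
  if (!class %in% names(lm$table)) stop("unknown class: ", class)
  lm$labels == lm$table[[class]]
}

#' Fold the six-class head labels to three classes
#'
#' Brain tissue labels (GM, WM, CSF) are folded into soft tissue, giving the
#' air / soft / bone partition used for reference attenuation maps and for
#' classification accuracy scoring.
#' @param lm a `suteac_labels` with six-class codes.
#' @return a `suteac_labels` over \{air, soft, bone\}.
#' @export
fold_to_three <- function(lm) {
  stopifnot(is_labels(lm))
  tc <- tissue_codes()
  lab <- lm$labels
  lab[lab %in% tc[c("gm", "wm", "csf")]] <- tc[["soft"]]
  label_mask(lab, tc[c("air", "soft", "bone")], lm$spacing, lm$origin)
}

labels_as_volume <- function(lm, units = "intensity") {
  volume(array(as.double(lm$labels), dim(lm$labels)), lm$spacing,
         lm$origin, units)
}
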