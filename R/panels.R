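#' T cell subset panels
#'
#' A clustering model is defined over an ordered panel of exactly four
#' T cell subsets. Two panels are predefined: `"gvhd_associated"`
#' (regulatory T cells, HLA-DR+ activated T cells, TCRab+ and TCRgd+
#' T cells) and `"broad_spectrum"` (CD4 helper, naive CD4 helper, CD8
#' cytotoxic, and CD45RO+ memory cytotoxic T cells). Custom four-subset
#' panels can be built by passing subset identifiers directly.
#'
#' @param name panel name: `"gvhd_associated"`, `"broad_spectrum"`, or a
#'   label for a custom panel.
#' @param subsets for a custom panel, an ordered character vector of
#'   exactly four subset identifiers; ignored for the predefined names.
#' @return An object of class `subset_panel`: the ordered character vector
#'   of subset identifiers with a `name` attribute.
#' @examples
#' subset_panel("gvhd_associated")
#' subset_panel("custom", c("CD3", "CD4", "CD8", "CD19"))
#' @export
subset_panel <- function(name = c("gvhd_associated", "broad_spectrum"),
                         subsets = NULL) {
  if (is.null(subsets)) {
    name <- match.arg(name)
    subsets <- switch(name,
      gvhd_associated = c("treg", "activated_t", "tcr_ab", "tcr_gd"),
      broad_spectrum  = c("cd4_helper", "cd4_naive", "cd8_cytotoxic",
                          "cd8_memory"))
  } else {
    stopifnot(is.character(name), length(name) == 1L)
  }
  subsets <- as.character(subsets)
  if (length(subsets) != 4L || anyDuplicated(subsets))
    stop("a subset panel must list exactly four distinct subsets")
  structure(subsets, name = name, class = "subset_panel")
}

#' @export
print.subset_panel <- function(x, ...) {
  cat("Subset panel '", attr(x, "name"), "': ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

panel_name <- function(panel) attr(panel, "name") %||% "custom"

# model index used in configuration ids ("1_1", "2_1", ...)
panel_model_index <- function(panel) {
  switch(panel_name(panel), gvhd_associated = "1", broad_spectrum = "2", "c")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
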