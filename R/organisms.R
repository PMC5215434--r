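#' Construct an ordered organism ladder with named epoch boundaries
#'
#' The comparative analyses in this package are all anchored on human:
#' reference organisms are ranked by their evolutionary distance to
#' *H. sapiens*, most recently diverged first. An *epoch boundary* `b` is the
#' cut-point after the `b`-th organism: a site "gained at boundary `b`" is a
#' lysine in human and in organisms `1..b`, and not a lysine beyond. Boundary
#' `0` denotes a human-specific state.
#'
#' @param names Character vector of organism names, most recently diverged
#'   first; must be unique.
#' @param depths Numeric vector of expected background substitutions per
#'   residue separating each organism from human; must be nonnegative and
#'   nondecreasing along the ladder.
#' @param epochs Named integer vector of epoch boundaries. Each value `b`
#'   (`0 <= b <= length(names)`) marks the cut between organisms `b` and
#'   `b + 1`.
#' @return An object of class `organism_order`: a list with elements
#'   `names`, `depths` and `epochs`.
#' @seealso [default_organism_order()] for the 14-organism ladder used
#'   throughout the package.
#' @export
organism_order <- function(names, depths, epochs = integer()) {
  if (length(names) == 0L) stop("organism_order: 'names' must be nonempty")
  if (anyDuplicated(names)) stop("organism_order: organism names must be unique")
  if (length(depths) != length(names))
    stop("organism_order: 'depths' must match 'names' in length")
  if (any(depths < 0)) stop("organism_order: 'depths' must be nonnegative")
  if (is.unsorted(depths)) {
    stop("organism_order: organisms must be ordered by nondecreasing divergence depth")
  }
  epochs <- stats::setNames(as.integer(epochs), names(epochs))
  if (length(epochs)) {
    if (is.null(names(epochs)) || any(!nzchar(names(epochs))))
      stop("organism_order: epoch boundaries must be named")
    if (any(epochs < 0L) || any(epochs > length(names)))
      stop("organism_order: epoch boundary outside the ladder")
  }
  structure(list(names = as.character(names), depths = as.numeric(depths),
                 epochs = epochs),
            class = "organism_order")
}

#' Default 14-organism ladder from gorilla to fission yeast
#'
#' The reference set spans *G. gorilla* to *S. pombe*, ordered by divergence
#' from human, with the five classical epoch boundaries (primate, mammalian,
#' vertebrate, animal, eukaryote) placed between the corresponding clades.
#' Depths are expected background amino-acid substitutions per residue and
#' act as the default divergence scale of the synthetic-data generator.
#'
#' @return An `organism_order` object with 14 organisms and 5 named epochs.
#' @export
default_organism_order <- function() {
  organism_order(
    names = c("G.gorilla", "M.mulatta", "R.norvegicus", "M.musculus",
              "G.gallus", "X.tropicalis", "D.rerio",
              "D.melanogaster", "A.gambiae", "C.elegans",
              "K.lactis", "S.cerevisiae", "N.crassa", "S.pombe"),
    depths = c(0.02, 0.06, 0.22, 0.23,
               0.75, 0.85, 1.05,
               1.75, 1.80, 1.90,
               2.40, 2.45, 2.50, 2.60),
    epochs = c(primate = 2L, mammalian = 4L, vertebrate = 7L,
               animal = 10L, eukaryote = 14L)
  )
}

#' @export
print.organism_order <- function(x, ...) {
  cat(sprintf("organism_order: %d organisms (%s ... %s)\n",
              length(x$names), x$names[1], x$names[length(x$names)]))
  if (length(x$epochs))
    cat("epochs:", paste(sprintf("%s=%d", names(x$epochs), x$epochs),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Human-readable label for an epoch boundary
#'
#' Returns the configured epoch name when boundary `b` coincides with one,
#' otherwise `"human"` for `b = 0` or `"after_<organism b>"`.
#'
#' @param b Integer boundary index, `0..n_organisms`.
#' @param order An `organism_order`.
#' @return Character label.
#' @export
epoch_label <- function(b, order) {
  stopifnot(inherits(order, "organism_order"))
  vapply(as.integer(b), function(bi) {
    if (is.na(bi)) return(NA_character_)
    if (bi < 0L || bi > length(order$names))
      stop("epoch_label: boundary outside the ladder")
    hit <- names(order$epochs)[match(bi, order$epochs)]
    if (!is.na(hit)) return(hit)
    if (bi == 0L) "human" else paste0("after_", order$names[bi])
  }, character(1))
}

#' Resolve an epoch name to its boundary index
#'
#' @param epoch Character epoch label (a configured name, `"human"`, or
#'   `"after_<organism>"`).
#' @param order An `organism_order`.
#' @return Integer boundary index.
#' @export
epoch_boundary <- function(epoch, order) {
  stopifnot(inherits(order, "organism_order"))
  vapply(as.character(epoch), function(e) {
    if (e %in% names(order$epochs)) return(order$epochs[[e]])
    if (identical(e, "human")) return(0L)
    if (startsWith(e, "after_")) {
      org <- sub("^after_", "", e)
      i <- match(org, order$names)
      if (!is.na(i)) return(i)
    }
    stop(sprintf("unknown epoch label '%s'", e))
  }, integer(1), USE.NAMES = FALSE)
}
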