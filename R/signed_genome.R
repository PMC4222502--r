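#' Signed genomes
#'
#' A signed genome represents one species' karyotype as an ordered set of
#' linear chromosomes, each an ordered vector of signed markers (conserved
#' segments such as `"C10"` or `"-C11"`; a leading `-` denotes reversed
#' orientation). Signed genomes are the unit of ancestral reconstruction and
#' of rearrangement simulation.
#'
#' @param species single species name.
#' @param chromosomes named (or unnamed) list of character vectors of signed
#'   markers; names are chromosome identifiers.
#' @return An object of class `signed_genome`: a list with elements
#'   `species` and `chromosomes`.
#' @examples
#' g <- signed_genome("dunnart", list(chr3 = c("C10", "C12", "C11")))
#' genome_markers(g)
#' @export
signed_genome <- function(species, chromosomes) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (!is.list(chromosomes)) stop("`chromosomes` must be a list of character vectors")
  if (is.null(names(chromosomes)) && length(chromosomes) > 0L) {
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  }
  chromosomes <- lapply(chromosomes, as.character)
  bad <- vapply(chromosomes, function(ch) length(ch) == 0L || any(!nzchar(gsub("^-", "", ch))),
                logical(1))
  if (any(bad)) stop("empty chromosome or empty marker symbol in genome for ", species)
  g <- structure(list(species = species, chromosomes = chromosomes),
                 class = "signed_genome")
  m <- genome_markers(g)
  if (anyDuplicated(m)) {
    stop("marker(s) repeated within genome '", species, "': ",
         paste(unique(m[duplicated(m)]), collapse = ", "))
  }
  g
}

#' @export
print.signed_genome <- function(x, ...) {
  cat("signed_genome:", x$species, "-", length(x$chromosomes), "chromosome(s),",
      length(genome_markers(x)), "marker(s)\n")
  for (nm in names(x$chromosomes)) {
    cat("  ", nm, ": ", paste(x$chromosomes[[nm]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Unsigned marker names of a signed genome
#' @param g a `signed_genome`.
#' @return character vector of marker names (signs stripped), in genome order.
#' @export
genome_markers <- function(g) {
  stopifnot(inherits(g, "signed_genome"))
  marker_name(unlist(g$chromosomes, use.names = FALSE))
}

#' Number of chromosomes of a signed genome
#' @param g a `signed_genome`.
#' @return integer chromosome count.
#' @export
n_chromosomes <- function(g) {
  stopifnot(inherits(g, "signed_genome"))
  length(g$chromosomes)
}

marker_name <- function(x) sub("^-", "", x)
marker_sign <- function(x) ifelse(grepl("^-", x), -1L, 1L)
flip_marker <- function(x) ifelse(grepl("^-", x), sub("^-", "", x), paste0("-", x))

## reverse a chromosome (or a slice): reverse order and flip all signs
reverse_markers <- function(ch) rev(flip_marker(ch))

## extremities: tail = "m:t", head = "m:h"; a +m chromosome segment is
## traversed tail -> head.  Left/right extremity of a signed marker:
left_extremity  <- function(x) paste0(marker_name(x), ifelse(marker_sign(x) > 0, ":t", ":h"))
right_extremity <- function(x) paste0(marker_name(x), ifelse(marker_sign(x) > 0, ":h", ":t"))

canonical_adjacency <- function(e1, e2) {
  a <- pmin(e1, e2); b <- pmax(e1, e2)
  paste(a, b, sep = "|")
}

#' Decompose a signed genome into marker-extremity adjacencies
#'
#' Each marker has two extremities (`tail`, `head`). A chromosome of k markers
#' yields k-1 internal adjacencies joining consecutive extremities, plus two
#' telomeric adjacencies pairing the outermost extremities with the telomere
#' pseudo-extremity `TEL`. Reversing a chromosome's written order yields the
#' identical adjacency set.
#'
#' @param g a `signed_genome`.
#' @param telomeres include telomeric adjacencies (default `TRUE`).
#' @return character vector of canonical adjacency strings `"ext1|ext2"`
#'   (extremities sorted within each adjacency); telomeric ones contain `"TEL"`.
#' @examples
#' g <- signed_genome("dunnart", list(chr3 = c("C10", "C12", "C11")))
#' genome_to_adjacencies(g, telomeres = FALSE)
#' @export
genome_to_adjacencies <- function(g, telomeres = TRUE) {
  stopifnot(inherits(g, "signed_genome"))
  adj <- character(0)
  for (ch in g$chromosomes) {
    k <- length(ch)
    if (k > 1L) {
      adj <- c(adj, canonical_adjacency(right_extremity(ch[-k]), left_extremity(ch[-1L])))
    }
    if (telomeres) {
      adj <- c(adj,
               canonical_adjacency("TEL", left_extremity(ch[1L])),
               canonical_adjacency("TEL", right_extremity(ch[k])))
    }
  }
  adj
}

## internal adjacencies as a two-column matrix of extremities (no telomeres)
internal_adjacency_pairs <- function(g) {
  out <- matrix(character(0), ncol = 2)
  for (ch in g$chromosomes) {
    k <- length(ch)
    if (k > 1L) out <- rbind(out, cbind(right_extremity(ch[-k]), left_extremity(ch[-1L])))
  }
  out
}

## canonical form of a genome: chromosomes canonicalized for direction
## (lexicographically smaller of the two readings) and sorted; used to test
## equality up to chromosome order and whole-chromosome reversal.
canonical_genome_string <- function(g) {
  chs <- vapply(g$chromosomes, function(ch) {
    fwd <- paste(ch, collapse = " ")
    bwd <- paste(reverse_markers(ch), collapse = " ")
    if (bwd < fwd) bwd else fwd
  }, character(1))
  paste(sort(chs), collapse = " ; ")
}

#' Test equality of two signed genomes up to chromosome order and reversal
#' @param a,b `signed_genome` objects.
#' @return logical.
#' @export
same_genome <- function(a, b) {
  canonical_genome_string(a) == canonical_genome_string(b)
}
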