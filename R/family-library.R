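#' Specify a repeat family
#'
#' Describes one repeat family of a synthetic repeatome: a tandem
#' satellite (head-to-tail monomer arrays) or a dispersed
#' retroelement-like repeat, optionally split into diverged subfamilies.
#' The defaults of [tribolium_like_families()] emulate a beetle genome
#' dominated by a 360-bp-monomer major satellite organized in five
#' subfamilies diverged up to 30%.
#'
#' @param name Family label.
#' @param monomer_length Monomer length in bp (>= 1).
#' @param genome_fraction Target fraction of the genome in `[0, 1]`.
#' @param n_subfamilies Number of subfamily consensuses (>= 1).
#' @param max_subfamily_divergence Maximum pairwise fraction of
#'   substituted positions between subfamily consensuses, in `[0, 1]`.
#' @param organization `"tandem"` (monomer arrays) or `"dispersed"`
#'   (isolated copies).
#' @param centromeric Should arrays be placed inside centromere
#'   intervals (with pericentromeric spill-over)?
#' @param array_bp Target array length in bp for tandem families; arrays
#'   get roughly this many bases each (at least one monomer).
#' @return A `repeat_family_spec` object.
#' @export
repeat_family_spec <- function(name, monomer_length, genome_fraction,
                               n_subfamilies = 1L,
                               max_subfamily_divergence = 0,
                               organization = c("tandem", "dispersed"),
                               centromeric = FALSE,
                               array_bp = 3000) {
  organization <- match.arg(organization)
  monomer_length <- as.integer(monomer_length)
  n_subfamilies <- as.integer(n_subfamilies)
  if (is.na(monomer_length) || monomer_length < 1L) {
    stop("invalid family spec: monomer_length must be >= 1")
  }
  if (is.na(n_subfamilies) || n_subfamilies < 1L) {
    stop("invalid family spec: n_subfamilies must be >= 1")
  }
  if (genome_fraction < 0 || genome_fraction > 1) {
    stop("invalid family spec: genome_fraction must be in [0, 1]")
  }
  if (max_subfamily_divergence < 0 || max_subfamily_divergence > 1) {
    stop("invalid family spec: max_subfamily_divergence must be in [0, 1]")
  }
  structure(
    list(name = name, monomer_length = monomer_length,
         genome_fraction = genome_fraction, n_subfamilies = n_subfamilies,
         max_subfamily_divergence = max_subfamily_divergence,
         organization = organization, centromeric = centromeric,
         array_bp = array_bp),
    class = "repeat_family_spec")
}

#' @export
print.repeat_family_spec <- function(x, ...) {
  cat(sprintf(
    "<repeat_family_spec> %s: %d bp monomer, %.3g%% of genome, %d subfamilies (<= %.0f%% diverged), %s%s\n",
    x$name, x$monomer_length, 100 * x$genome_fraction, x$n_subfamilies,
    100 * x$max_subfamily_divergence, x$organization,
    if (x$centromeric) ", centromeric" else ""))
  invisible(x)
}

#' Build subfamily consensus sequences for a repeat family
#'
#' A random ancestor monomer is mutated by substitutions at distinct,
#' uniformly chosen positions.  Subfamily `i` (of `n`) diverges from the
#' ancestor by `max_subfamily_divergence / 2 * (i - 1) / (n - 1)`, so
#' every pairwise consensus divergence is at most
#' `max_subfamily_divergence` while the most distant pairs approach it.
#' With zero divergence all consensuses are identical.
#'
#' @param spec A [repeat_family_spec()].
#' @param seed Integer seed; generation is reproducible from
#'   `(spec, seed)`.
#' @return Named character vector of `n_subfamilies` consensus
#'   sequences, each of length `monomer_length`.
#' @export
build_family_library <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "repeat_family_spec"))
  withr_seed(seed, {
    m <- spec$monomer_length
    n <- spec$n_subfamilies
    ancestor <- strsplit(random_dna(m), "")[[1]]
    div <- if (n == 1) 0 else
      spec$max_subfamily_divergence / 2 * (seq_len(n) - 1) / (n - 1)
    out <- vapply(seq_len(n), function(i) {
      k <- round(div[i] * m)
      s <- ancestor
      if (k > 0) {
        pos <- sample.int(m, k)
        s[pos] <- vapply(s[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    names(out) <- paste0(spec$name, "_sub", seq_len(n))
    out
  })
}

#' Pairwise divergence between equal-length sequences
#'
#' Fraction of positions at which two sequences differ, by direct
#' position-wise comparison.
#'
#' @param a,b DNA strings of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
sequence_divergence <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) stop("sequences must have equal length")
  mean(va != vb)
}

# Evaluate expr with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
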