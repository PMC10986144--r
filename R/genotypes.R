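# Strategy space: three binary loci -> 8 genotypes.
# Internal integer code packs the loci as bits: C = 1, S = 2, R = 4.

.qs_allele <- c("csr", "Csr", "CSr", "CsR", "CSR", "cSr", "cSR", "csR")
.qs_short  <- c("La",  "Tr",  "Bo",  "Sm",  "Ne",  "Li",  "Cl",  "Vo")
.qs_name   <- c("Lazy", "Trusty", "Bouncer", "Smart", "Nerd",
                "Liar", "Curious liar", "Voyeur")
.qs_code   <- c(0L, 1L, 3L, 5L, 7L, 2L, 6L, 4L)

#' The eight quorum-sensing strategies
#'
#' Strategies are defined by three binary loci: a cooperation locus (`C`),
#' an extra-signal locus (`S`) and a signal-response locus (`R`). A functional
#' `C` locus also emits one constitutive signal dose (the cue), so cooperators
#' advertise cooperation for free while non-cooperators must carry `S` (and
#' pay `s`) to fake it. Carriers of both `C` and `R` are conditional
#' cooperators: they express cooperation only when the local signal dose count
#' reaches the quorum threshold `Q`.
#'
#' @return A tibble with one row per genotype: `allele` (canonical three-letter
#'   string, e.g. `"CsR"`), `short` (two-letter strategy tag, e.g. `"Sm"`),
#'   `name` (full strategy name), the three locus indicators `has_C`, `has_S`,
#'   `has_R`, and the derived classification columns
#'   `conditional_cooperator` (`C` and `R`) and
#'   `unconditional_cooperator` (`C` and not `R`).
#' @examples
#' qs_genotypes()
#' @export
qs_genotypes <- function() {
  has_C <- bitwAnd(.qs_code, 1L) > 0L
  has_S <- bitwAnd(.qs_code, 2L) > 0L
  has_R <- bitwAnd(.qs_code, 4L) > 0L
  tibble::tibble(
    allele = .qs_allele,
    short = .qs_short,
    name = .qs_name,
    has_C = has_C,
    has_S = has_S,
    has_R = has_R,
    conditional_cooperator = has_C & has_R,
    unconditional_cooperator = has_C & !has_R
  )
}

#' Normalise genotype labels to canonical allele strings
#'
#' Accepts canonical allele strings (`"CsR"`), two-letter strategy tags
#' (`"Sm"`) or full names (`"Smart"`, case-insensitive), in any mix.
#'
#' @param x character vector of genotype labels.
#' @return Character vector of canonical allele strings.
#' @examples
#' as_genotype(c("Smart", "La", "CSr"))
#' @export
as_genotype <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  stopifnot(is.character(x))
  out <- rep(NA_character_, length(x))
  # allele strings are case-sensitive (the case IS the allele state)
  m <- match(x, .qs_allele)
  out[!is.na(m)] <- .qs_allele[m[!is.na(m)]]
  todo <- is.na(out)
  if (any(todo)) {
    m <- match(tolower(x[todo]), tolower(.qs_short))
    out[todo][!is.na(m)] <- .qs_allele[m[!is.na(m)]]
  }
  todo <- is.na(out)
  if (any(todo)) {
    m <- match(tolower(x[todo]), tolower(.qs_name))
    out[todo][!is.na(m)] <- .qs_allele[m[!is.na(m)]]
  }
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

# allele string <-> internal bit code
genotype_code <- function(x) .qs_code[match(as_genotype(x), .qs_allele)]
genotype_from_code <- function(code) .qs_allele[match(code, .qs_code)]

genotype_has_C <- function(x) bitwAnd(genotype_code(x), 1L) > 0L
genotype_has_S <- function(x) bitwAnd(genotype_code(x), 2L) > 0L
genotype_has_R <- function(x) bitwAnd(genotype_code(x), 4L) > 0L

#' @rdname qs_genotypes
#' @param x character vector of genotype labels (any accepted form).
#' @export
is_conditional_cooperator <- function(x) {
  genotype_has_C(x) & genotype_has_R(x)
}

#' @rdname qs_genotypes
#' @export
is_unconditional_cooperator <- function(x) {
  genotype_has_C(x) & !genotype_has_R(x)
}

#' Build an interaction-group composition
#'
#' An interaction group is a multiset of `N` genotypes, the focal individual
#' included. Input is either a vector of `N` genotype labels or a named count
#' vector (`c(Tr = 3, La = 6)`).
#'
#' @param x character vector of member genotypes, or a named numeric vector of
#'   counts per genotype.
#' @param N expected group size; defaults to the total supplied.
#' @return Named integer vector of counts over the 8 canonical allele strings,
#'   summing to `N`.
#' @examples
#' qs_group(c(Tr = 3, La = 6))
#' qs_group(c("Smart", "La", "La", "La", "La", "La", "La", "La", "Tr"))
#' @export
qs_group <- function(x, N = NULL) {
  counts <- stats::setNames(integer(8L), .qs_allele)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    g <- as_genotype(names(x))
    v <- as.integer(x)
    if (any(v < 0)) stop("group counts must be non-negative", call. = FALSE)
    for (i in seq_along(g)) counts[g[i]] <- counts[g[i]] + v[i]
  } else {
    tab <- table(as_genotype(x))
    counts[names(tab)] <- as.integer(tab)
  }
  if (!is.null(N) && sum(counts) != N) {
    stop("group totals ", sum(counts), ", expected N = ", N, call. = FALSE)
  }
  counts
}

# validate a counts vector against params$N
check_group <- function(group, params) {
  if (is.null(names(group)) || !all(names(group) %in% .qs_allele) ||
      length(group) != 8L) {
    group <- qs_group(group)
  }
  group <- group[.qs_allele]
  if (sum(group) != params$N) {
    stop("invalid group: totals ", sum(group), " but N = ", params$N,
         call. = FALSE)
  }
  group
}
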