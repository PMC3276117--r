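# Site specifications, canonical haplotype/diplotype serialization, and
# enumeration of the diplotypes consistent with an unphased observation.
#
# Serialization conventions (shared by every reader/writer in the package):
#   * ICN allele:  decimal copy count, e.g. "0", "2"
#   * SNVC allele: copy units sorted by alphabet order, comma-joined,
#                  e.g. "A,A"; the empty multiset (a deletion) is "-"
#   * SNP allele:  a single base, e.g. "a"
#   * haplotype:   per-site allele strings joined by "_"
#   * diplotype:   "h1/h2" with h1 <= h2 in C-locale string order
#   * unphased state: ICN total as decimal; SNVC total base multiset as a
#     sorted bare string ("AAG", "-" for zero copies); SNP genotype as a
#     sorted two-base string ("at")

SITE_TYPES <- c("ICN", "SNVC", "SNP")

#' Define the sites of a CNV region
#'
#' A site is an abstract locus at which a haplotype carries either an integer
#' copy number (`ICN`), a multiset of copy-unit bases (`SNVC`), or a single
#' base (`SNP`). Site order in the table fixes the order in which per-site
#' alleles are joined (by `_`) into haplotype strings.
#'
#' @param site_id Character vector of unique site identifiers.
#' @param site_type Character vector, each one of `"ICN"`, `"SNVC"`, `"SNP"`.
#' @param alphabet Comma-joined single-character base symbols for SNVC/SNP
#'   sites (e.g. `"A,B"`); ignored (may be `""`) for ICN sites.
#' @param max_total_copies Cap on the summed copy number over a diplotype
#'   (default 4).
#' @param max_allele_copies Cap on copies carried by one haplotype
#'   (default 2). SNP sites always carry exactly one copy per haplotype.
#' @return A `data.frame` of class `cnv_sites`, one row per site.
#' @examples
#' cnv_sites(c("del1", "snp1"), c("ICN", "SNP"), c("", "a,t"))
#' @export
cnv_sites <- function(site_id, site_type, alphabet = "",
                      max_total_copies = 4L, max_allele_copies = 2L) {
  n <- length(site_id)
  sites <- data.frame(
    site_id = as.character(site_id),
    site_type = as.character(site_type),
    alphabet = rep_len(as.character(alphabet), n),
    max_total_copies = as.integer(rep_len(max_total_copies, n)),
    max_allele_copies = as.integer(rep_len(max_allele_copies, n)),
    stringsAsFactors = FALSE
  )
  validate_sites(sites)
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  needed <- c("site_id", "site_type", "alphabet",
              "max_total_copies", "max_allele_copies")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop("sites table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in sites table")
  bad <- !sites$site_type %in% SITE_TYPES
  if (any(bad)) {
    stop("unknown site_type: ", paste(unique(sites$site_type[bad]), collapse = ", "))
  }
  if (any(sites$max_total_copies < 0L) || any(sites$max_allele_copies < 0L)) {
    stop("copy-number caps must be non-negative")
  }
  for (i in seq_len(nrow(sites))) {
    if (sites$site_type[i] != "ICN") {
      ab <- site_alphabet(sites[i, ])
      if (!length(ab)) stop("site ", sites$site_id[i], ": alphabet required")
      if (any(nchar(ab) != 1L)) {
        stop("site ", sites$site_id[i], ": alphabet symbols must be single characters")
      }
      if (anyDuplicated(ab)) stop("site ", sites$site_id[i], ": duplicated alphabet symbol")
      if ("-" %in% ab) stop("site ", sites$site_id[i], ": '-' is reserved for deletions")
    }
  }
  class(sites) <- c("cnv_sites", "data.frame")
  sites
}

site_alphabet <- function(site) {
  ab <- site$alphabet[1]
  if (is.na(ab) || !nzchar(ab)) return(character(0))
  strsplit(ab, ",", fixed = TRUE)[[1]]
}

# ---- allele / state parsing -------------------------------------------------

# SNVC multisets are handled as sorted character vectors of single bases;
# character(0) is the deletion.

parse_snvc <- function(x, alphabet, what = "state") {
  if (x == "-" || !nzchar(x)) return(character(0))
  units <- if (grepl(",", x, fixed = TRUE)) {
    strsplit(x, ",", fixed = TRUE)[[1]]
  } else {
    strsplit(x, "", fixed = TRUE)[[1]]
  }
  bad <- setdiff(units, alphabet)
  if (length(bad)) {
    stop("symbol(s) outside site alphabet in ", what, " '", x, "': ",
         paste(bad, collapse = ", "))
  }
  sort_by_alphabet(units, alphabet)
}

sort_by_alphabet <- function(units, alphabet) {
  units[order(match(units, alphabet))]
}

snvc_allele_string <- function(units) {
  if (!length(units)) "-" else paste(units, collapse = ",")
}

snvc_state_string <- function(units) {
  if (!length(units)) "-" else paste(units, collapse = "")
}

parse_icn <- function(x, what = "state") {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("non-integer ICN ", what, ": '", x, "'")
  if (v < 0L) stop("negative ICN ", what, ": ", v)
  v
}

# ---- canonical haplotype / diplotype strings --------------------------------

#' Canonical diplotype string
#'
#' Joins two haplotype strings into the canonical unordered-pair form
#' `"h1/h2"`, ordering the pair lexicographically so that `[h1/h2]` and
#' `[h2/h1]` compare equal.
#'
#' @param h1,h2 Character vectors of haplotype strings (recycled).
#' @return Character vector of canonical diplotype strings.
#' @examples
#' diplotype_string("3", "0")   # "0/3"
#' @export
diplotype_string <- function(h1, h2) {
  if (!length(h1) && !length(h2)) return(character(0))
  swap <- cstring_gt(h1, h2)
  lo <- ifelse(swap, h2, h1)
  hi <- ifelse(swap, h1, h2)
  paste0(lo, "/", hi)
}

# locale-independent string comparison (C collation) so canonical order is
# identical across platforms
cstring_gt <- function(a, b) {
  prev <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a > b
}

csort <- function(x) {
  prev <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

split_diplotype <- function(d) {
  parts <- strsplit(d, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed diplotype string: ", d[bad][1])
  list(h1 = vapply(parts, `[`, "", 1L), h2 = vapply(parts, `[`, "", 2L))
}

haplotype_alleles <- function(h, n_sites) {
  parts <- strsplit(h, "_", fixed = TRUE)
  bad <- lengths(parts) != n_sites
  if (any(bad)) {
    stop("haplotype '", h[bad][1], "' does not have ", n_sites, " site(s)")
  }
  parts
}

# ---- per-site enumeration ---------------------------------------------------

#' Enumerate one-site diplotypes consistent with a total copy number
#'
#' Every unordered pair of per-haplotype copy counts `(a, b)` with
#' `a + b = total_copies` and both counts within the per-haplotype cap. A
#' total of 3 yields `[0/3]` and `[1/2]` when the cap allows 3 copies.
#'
#' @param total_copies Observed total copy number (non-negative integer).
#' @param site One row of a [cnv_sites()] table with `site_type == "ICN"`.
#' @return Two-column character matrix (`h1`, `h2`) of per-site allele
#'   strings, one row per diplotype; zero rows if the caps admit no
#'   decomposition.
#' @examples
#' site <- cnv_sites("s", "ICN", max_allele_copies = 3)
#' enumerate_icn_diplotypes(3, site)
#' @export
enumerate_icn_diplotypes <- function(total_copies, site) {
  total <- parse_icn(total_copies)
  cap <- site$max_allele_copies[1]
  a <- 0:(total %/% 2L)
  b <- total - a
  keep <- a <= cap & b <= cap
  cbind(h1 = as.character(a[keep]), h2 = as.character(b[keep]))
}

#' Enumerate one-site diplotypes consistent with an unphased SNVC genotype
#'
#' All unordered two-part multiset partitions of the observed base multiset,
#' each part within the per-haplotype copy cap. The genotype `AAG` yields
#' `[-/A,A,G]`, `[A,A/G]` and `[A/A,G]` (cap permitting).
#'
#' @param state Unphased genotype as a base string (`"AAG"`) or `"-"` for
#'   zero copies.
#' @param site One row of a [cnv_sites()] table with `site_type == "SNVC"`.
#' @return Two-column character matrix of per-site allele strings.
#' @export
enumerate_snvc_diplotypes <- function(state, site) {
  alphabet <- site_alphabet(site)
  units <- parse_snvc(state, alphabet)
  cap <- site$max_allele_copies[1]
  counts <- tabulate(match(units, alphabet), nbins = length(alphabet))
  # part-1 count vectors over the alphabet: 0..count per symbol
  grids <- lapply(counts, function(k) 0:k)
  part1 <- as.matrix(expand.grid(grids))
  size1 <- rowSums(part1)
  size2 <- sum(counts) - size1
  keep <- size1 <= cap & size2 <= cap
  part1 <- part1[keep, , drop = FALSE]
  seen <- character(0)
  out <- matrix(character(0), 0, 2, dimnames = list(NULL, c("h1", "h2")))
  for (r in seq_len(nrow(part1))) {
    u1 <- rep(alphabet, part1[r, ])
    u2 <- rep(alphabet, counts - part1[r, ])
    a1 <- snvc_allele_string(u1)
    a2 <- snvc_allele_string(u2)
    d <- diplotype_string(a1, a2)
    if (d %in% seen) next
    seen <- c(seen, d)
    sp <- split_diplotype(d)
    out <- rbind(out, c(sp$h1, sp$h2))
  }
  out
}

#' Enumerate the one-site diplotype of an unphased SNP genotype
#'
#' A SNP genotype has no phase ambiguity on its own: `{a,t}` maps to the
#' single diplotype `[a/t]`.
#'
#' @param state Two-base genotype string, e.g. `"at"`.
#' @param site One row of a [cnv_sites()] table with `site_type == "SNP"`.
#' @return Two-column character matrix with one row.
#' @export
enumerate_snp_diplotypes <- function(state, site) {
  alphabet <- site_alphabet(site)
  bases <- strsplit(state, "", fixed = TRUE)[[1]]
  if (length(bases) != 2L) stop("SNP state must be two bases: '", state, "'")
  bad <- setdiff(bases, alphabet)
  if (length(bad)) {
    stop("symbol(s) outside site alphabet in state '", state, "': ",
         paste(bad, collapse = ", "))
  }
  bases <- csort(bases)
  cbind(h1 = bases[1], h2 = bases[2])
}

#' Enumerate one-site diplotypes for any site type
#'
#' Dispatches on the site's `site_type` to the ICN, SNVC or SNP enumerator.
#'
#' @param state Unphased state string in the site's dialect.
#' @param site One row of a [cnv_sites()] table.
#' @return Two-column character matrix of per-site allele strings.
#' @export
enumerate_site_diplotypes <- function(state, site) {
  switch(site$site_type[1],
    ICN = enumerate_icn_diplotypes(state, site),
    SNVC = enumerate_snvc_diplotypes(state, site),
    SNP = enumerate_snp_diplotypes(state, site),
    stop("unknown site_type: ", site$site_type[1])
  )
}

# ---- multi-site expansion ---------------------------------------------------

#' Expand per-site diplotype sets into multi-site diplotypes
#'
#' Combines one one-site diplotype per site in every orientation (either
#' haplotype of the one-site pair may sit on either chromosome), then
#' deduplicates under a global swap of the two chromosomes. With per-site
#' sets `{[0/3],[1/2]}` and `{[a/t]}` this yields `[0_a/3_t]`, `[0_t/3_a]`,
#' `[1_a/2_t]` and `[1_t/2_a]`.
#'
#' @param per_site_sets List (one element per site, in site order) of
#'   two-column character matrices as returned by
#'   [enumerate_site_diplotypes()].
#' @return Two-column character matrix (`h1`, `h2`) of multi-site haplotype
#'   strings (alleles joined by `_`), `h1 <= h2` canonically, deduplicated.
#' @export
expand_multisite <- function(per_site_sets) {
  if (!length(per_site_sets)) stop("no per-site diplotype sets given")
  empty <- vapply(per_site_sets, function(m) nrow(m) == 0L, TRUE)
  if (any(empty)) {
    stop("no consistent one-site diplotype at site index ",
         which(empty)[1], "; individual has no consistent diplotype")
  }
  # grow unordered partial pairs site by site; deduplication of unordered
  # partial pairs is sound because the two extension orientations are
  # symmetric in the pair
  pairs <- matrix("", 1, 2)
  for (s in seq_along(per_site_sets)) {
    m <- per_site_sets[[s]]
    sep <- if (s == 1L) "" else "_"
    h1 <- c(paste0(rep(pairs[, 1], each = nrow(m)), sep, m[, 1]),
            paste0(rep(pairs[, 1], each = nrow(m)), sep, m[, 2]))
    h2 <- c(paste0(rep(pairs[, 2], each = nrow(m)), sep, m[, 2]),
            paste0(rep(pairs[, 2], each = nrow(m)), sep, m[, 1]))
    key <- diplotype_string(h1, h2)
    keep <- !duplicated(key)
    sp <- split_diplotype(key[keep])
    pairs <- cbind(sp$h1, sp$h2)
  }
  colnames(pairs) <- c("h1", "h2")
  pairs
}

# ---- collapsing back to unphased states -------------------------------------

combine_alleles <- function(a1, a2, site) {
  switch(site$site_type[1],
    ICN = as.character(parse_icn(a1, "allele") + parse_icn(a2, "allele")),
    SNVC = {
      ab <- site_alphabet(site)
      snvc_state_string(sort_by_alphabet(
        c(parse_snvc(a1, ab, "allele"), parse_snvc(a2, ab, "allele")), ab))
    },
    SNP = paste(csort(c(a1, a2)), collapse = ""),
    stop("unknown site_type")
  )
}

#' Collapse diplotypes to their per-site unphased states
#'
#' The inverse of enumeration: sums copy counts (ICN), merges base multisets
#' (SNVC), or forms the unordered genotype (SNP) at each site.
#'
#' @param h1,h2 Character vectors of multi-site haplotype strings.
#' @param sites A [cnv_sites()] table.
#' @return Character matrix, one row per diplotype, one column per site,
#'   holding unphased state strings.
#' @export
collapse_diplotypes <- function(h1, h2, sites) {
  n_sites <- nrow(sites)
  al1 <- haplotype_alleles(h1, n_sites)
  al2 <- haplotype_alleles(h2, n_sites)
  out <- matrix("", length(h1), n_sites,
                dimnames = list(NULL, sites$site_id))
  for (s in seq_len(n_sites)) {
    site <- sites[s, ]
    a1 <- vapply(al1, `[`, "", s)
    a2 <- vapply(al2, `[`, "", s)
    # vectorize over unique allele pairs
    key <- paste(a1, a2, sep = "\r")
    uk <- unique(key)
    states <- vapply(strsplit(uk, "\r", fixed = TRUE),
                     function(p) combine_alleles(p[1], p[2], site), "")
    out[, s] <- states[match(key, uk)]
  }
  out
}

#' Enumerate all unphased states a site can show
#'
#' Every state reachable by some diplotype under the site's caps: totals
#' `0..max_total_copies` (ICN), all base multisets of size up to
#' `max_total_copies` (SNVC), or all unordered base pairs (SNP).
#'
#' @param site One row of a [cnv_sites()] table.
#' @return Character vector of state strings.
#' @export
enumerate_states <- function(site) {
  switch(site$site_type[1],
    ICN = as.character(0:site$max_total_copies[1]),
    SNVC = {
      ab <- site_alphabet(site)
      cap <- site$max_total_copies[1]
      out <- "-"
      for (size in seq_len(cap)) {
        combos <- multisets_of_size(ab, size)
        out <- c(out, vapply(combos, snvc_state_string, ""))
      }
      out
    },
    SNP = {
      ab <- csort(site_alphabet(site))
      idx <- which(upper.tri(diag(length(ab)), diag = TRUE), arr.ind = TRUE)
      paste0(ab[idx[, 1]], ab[idx[, 2]])
    },
    stop("unknown site_type")
  )
}

# all multisets of `size` elements over `alphabet`, as sorted vectors
multisets_of_size <- function(alphabet, size) {
  if (size == 0L) return(list(character(0)))
  idx <- utils::combn(length(alphabet) + size - 1L, size, simplify = FALSE)
  lapply(idx, function(pos) {
    # stars-and-bars: position minus rank gives the symbol index
    alphabet[pos - seq_len(size) + 1L]
  })
}
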