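# Sequence ingestion and the codon-aware quality screen applied to mtCOI
# data before any statistic is computed. Sequences arising from nuclear
# mitochondrial insertions (NUMTs) betray themselves by frame-shifting
# indels or unexpected internal stop codons; both are screened here.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Read aligned DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of sequence records. Header lines may
#' carry metadata as whitespace-separated `key=value` tokens after the id
#' (keys `species`, `region`, `site`); metadata can instead be joined later
#' from a sample sheet ([read_sample_sheet()]).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `species`, `region`, `site`, `seq`
#'   (uppercase, IUPAC DNA codes and `-`), one row per entry, input order
#'   preserved.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no sequences in ", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  }
  meta_of <- function(key) {
    vapply(headers, function(h) {
      m <- regmatches(h, regexec(paste0("(?:^|\\s)", key, "=([^\\s]+)"),
                                 h))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  for (i in seq_along(seqs)) {
    bad <- which(!strsplit(seqs[i], "")[[1]] %in% IUPAC_DNA)
    if (length(bad)) {
      abort(sprintf("non-IUPAC character '%s' in sequence '%s' at position %d",
                    substr(seqs[i], bad[1], bad[1]), ids[i], bad[1]))
    }
  }
  tibble(
    id = ids,
    species = meta_of("species"),
    region  = meta_of("region"),
    site    = meta_of("site"),
    seq = unname(seqs)
  )
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: metadata columns are emitted as `key=value`
#' header tokens when present.
#'
#' @param records Tibble with columns `id` and `seq` (and optionally
#'   `species`, `region`, `site`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- records$id
  for (key in c("species", "region", "site")) {
    if (key %in% names(records)) {
      v <- records[[key]]
      hdr <- ifelse(is.na(v), hdr, paste0(hdr, " ", key, "=", v))
    }
  }
  set <- Biostrings::BStringSet(setNames(records$seq, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read or write a sample sheet
#'
#' A sample sheet is a TSV with columns `id`, `species`, `region`, `site`
#' mapping sequence ids to their population of origin.
#'
#' @param path Path to a TSV file.
#' @return A tibble with those four character columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("id", "species", "region", "site")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) {
    abort(paste0("sample sheet lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sheet[need]
}

#' @rdname read_sample_sheet
#' @param sheet Tibble to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Construct a codon alignment
#'
#' Bundles equal-length aligned coding sequences with their reading-frame
#' context. All downstream statistics take either this object or a
#' [population_sample()] derived from it.
#'
#' @param records Tibble as returned by [read_fasta()]; all `seq` values must
#'   have equal (aligned) length.
#' @param frame_offset Number of alignment columns (0, 1 or 2) before the
#'   first complete codon. Frame detection is deliberately not automatic.
#' @param genetic_code Code identifier, see [genetic_code()].
#' @return The records tibble with class `codon_alignment` and attributes
#'   `frame_offset` and `genetic_code`.
#' @export
codon_alignment <- function(records, frame_offset = 0L,
                            genetic_code = "invertebrate_mito") {
  if (nrow(records) == 0L) abort("no sequences")
  lens <- nchar(records$seq)
  if (length(unique(lens)) != 1L) {
    abort("sequences have unequal aligned lengths")
  }
  if (!frame_offset %in% 0:2) abort("frame_offset must be 0, 1 or 2")
  genetic_code(genetic_code)  # validates the identifier
  structure(as_tibble(records),
            frame_offset = as.integer(frame_offset),
            genetic_code = genetic_code,
            class = c("codon_alignment", class(as_tibble(records))))
}

aln_length <- function(aln) nchar(aln$seq[1])
aln_frame <- function(aln) attr(aln, "frame_offset") %||% 0L
aln_code <- function(aln) attr(aln, "genetic_code") %||% "invertebrate_mito"

#' Codon-aware ORF screen
#'
#' Flags sequences whose reading frame is broken: internal gap runs whose
#' length is not a multiple of three (frame-shift indels) or internal stop
#' codons under the alignment's genetic code. Both patterns are the
#' classical signature of a nuclear mitochondrial insertion rather than a
#' functional mtCOI copy.
#'
#' @param aln A [codon_alignment()].
#' @return A tibble with columns `id`, `pass` (logical), `reason`
#'   (`NA`, `"frame shift"` or `"internal stop"`), `codon` (1-based index of
#'   the first offending codon, `NA` otherwise).
#' @export
screen_orf <- function(aln) {
  offset <- aln_frame(aln)
  code <- aln_code(aln)
  one <- function(seq) {
    body <- substr(seq, offset + 1L, nchar(seq))
    chars <- strsplit(body, "")[[1]]
    nongap <- which(chars != "-")
    if (length(nongap) == 0L) {
      return(list(pass = FALSE, reason = "frame shift", codon = NA_integer_))
    }
    inner <- chars[nongap[1]:nongap[length(nongap)]]
    runs <- rle(inner == "-")
    gap_runs <- runs$lengths[runs$values]
    if (any(gap_runs %% 3L != 0L)) {
      return(list(pass = FALSE, reason = "frame shift", codon = NA_integer_))
    }
    ungapped <- paste(inner[inner != "-"], collapse = "")
    n_cod <- nchar(ungapped) %/% 3L
    if (n_cod == 0L) {
      return(list(pass = TRUE, reason = NA_character_, codon = NA_integer_))
    }
    aa <- rep(NA_character_, n_cod)
    codons <- substring(ungapped, seq(1L, by = 3L, length.out = n_cod),
                        seq(3L, by = 3L, length.out = n_cod))
    clean <- grepl("^[ACGT]{3}$", codons)
    aa[clean] <- genetic_code(code)[codons[clean]]
    internal_stop <- which(aa == "*")
    internal_stop <- internal_stop[internal_stop < n_cod]
    if (length(internal_stop)) {
      return(list(pass = FALSE, reason = "internal stop",
                  codon = internal_stop[1]))
    }
    list(pass = TRUE, reason = NA_character_, codon = NA_integer_)
  }
  res <- map(aln$seq, one)
  tibble(
    id = aln$id,
    pass = map_lgl(res, "pass"),
    reason = map_chr(res, "reason"),
    codon = map_int(res, "codon")
  )
}

#' Complete-case site mask
#'
#' Returns the alignment columns at which every sequence of a subset carries
#' an unambiguous base (A/C/G/T; gaps and IUPAC ambiguities are treated as
#' missing). These are the "sites used" over which all per-population
#' statistics are computed.
#'
#' @param aln A [codon_alignment()].
#' @param ids Sequence ids defining the subset (default: all).
#' @return Strictly increasing integer vector of 1-based column indices,
#'   with attribute `n_total` = alignment length.
#' @export
complete_sites <- function(aln, ids = NULL) {
  if (is.null(ids)) ids <- aln$id
  if (length(ids) == 0L) abort("empty subset")
  miss <- setdiff(ids, aln$id)
  if (length(miss)) abort(paste0("unknown id(s): ", paste(miss, collapse = ", ")))
  seqs <- aln$seq[match(ids, aln$id)]
  m <- do.call(rbind, strsplit(seqs, ""))
  ok <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == nrow(m)
  used <- which(ok)
  if (length(used) == 0L) abort("no usable sites")
  structure(used, n_total = ncol(m))
}

#' Extract one population from an alignment
#'
#' Subsets a codon alignment to the specimens of one (species, site)
#' population using a sample sheet, computes its complete-case site mask,
#' and applies the minimum-sample-size gate: populations with fewer than
#' `min_n` sequences are kept (their counts are still reported) but flagged
#' `excluded` so that estimation steps skip them.
#'
#' @param aln A [codon_alignment()].
#' @param sheet Sample sheet tibble (`id`, `species`, `region`, `site`).
#' @param species,site Population label to extract.
#' @param min_n Estimation gate (default 4 specimens).
#' @return A `pop_sample` object: list with `records`, `mask`, `excluded`,
#'   `species`, `region`, `site`, `frame_offset`, `genetic_code`,
#'   `sites_alignment`.
#' @export
subsample_population <- function(aln, sheet, species, site, min_n = 4L) {
  rows <- sheet[sheet$species == species & sheet$site == site, ]
  if (nrow(rows) == 0L) {
    abort(paste0("no specimens for species '", species, "' at site '", site, "'"))
  }
  ids <- intersect(rows$id, aln$id)
  if (length(ids) == 0L) {
    abort(paste0("sample sheet ids for '", species, "'/'", site,
                 "' not present in the alignment"))
  }
  population_sample(aln, ids,
                    species = species, site = site,
                    region = rows$region[1], min_n = min_n)
}

#' Build a population sample from explicit ids
#'
#' Lower-level companion of [subsample_population()] for when the subset is
#' already known.
#'
#' @inheritParams subsample_population
#' @param ids Sequence ids in the population.
#' @param region Optional region label.
#' @export
population_sample <- function(aln, ids = NULL, species = NA_character_,
                              site = NA_character_, region = NA_character_,
                              min_n = 4L) {
  if (is.null(ids)) ids <- aln$id
  mask <- complete_sites(aln, ids)
  records <- aln[match(ids, aln$id), , drop = FALSE]
  structure(list(
    records = as_tibble(records),
    mask = mask,
    excluded = length(ids) < min_n,
    species = species, region = region, site = site,
    frame_offset = aln_frame(aln),
    genetic_code = aln_code(aln),
    sites_alignment = aln_length(aln)
  ), class = "pop_sample")
}

#' @export
print.pop_sample <- function(x, ...) {
  cat("<pop_sample> ", nrow(x$records), " sequences",
      if (!is.na(x$species)) paste0(" of ", x$species) else "",
      if (!is.na(x$site)) paste0(" at ", x$site) else "",
      "; ", length(x$mask), "/", x$sites_alignment, " sites used",
      if (x$excluded) "; excluded from estimation (n < 4)" else "",
      "\n", sep = "")
  invisible(x)
}

# n x |mask| character matrix of the masked alignment columns.
as_seq_matrix <- function(pop) {
  m <- do.call(rbind, strsplit(pop$records$seq, ""))[, pop$mask, drop = FALSE]
  rownames(m) <- pop$records$id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
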