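# End-to-end orchestration: QC -> diversity -> demography -> F_ST ->
# haplotype networks, with every table written as TSV and every stochastic
# stage seeded explicitly so a rerun is byte-identical.

#' Run the full mtCOI population-genetics pipeline
#'
#' Reads a FASTA + sample sheet (or takes an in-memory alignment), applies
#' the codon-aware ORF screen, and produces the per-population diversity
#' and demography tables, per-species F_ST with permutation P-values, and
#' per-species haplotype networks. All outputs are written under
#' `out_dir`; the returned bundle carries the same objects in memory.
#'
#' @param fasta,sheet Paths to a FASTA file and TSV sample sheet, or `NULL`
#'   if `aln` is given.
#' @param aln Optional in-memory [codon_alignment()] (metadata columns
#'   used as the sample sheet).
#' @param out_dir Output directory.
#' @param frame_offset Reading-frame offset of the alignment.
#' @param seed Master seed for all stochastic stages (mandatory).
#' @param reps Replicates for coalescent tests and permutation tests.
#' @param min_n Per-population estimation gate (default 4).
#' @param drop_failed_qc Drop sequences failing [screen_orf()] before
#'   analysis (default TRUE).
#' @return Invisibly, a list with `qc`, `diversity`, `demography`, `fst`,
#'   `networks`, `paths`, `log`.
#' @export
run_pipeline <- function(fasta = NULL, sheet = NULL, aln = NULL,
                         out_dir, frame_offset = 0L, seed, reps = 1000L,
                         min_n = 4L, drop_failed_qc = TRUE) {
  if (missing(seed)) abort("seed is mandatory")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  if (is.null(aln)) {
    records <- stage("read", read_fasta(fasta))
    meta <- stage("read", read_sample_sheet(sheet))
    records$species <- meta$species[match(records$id, meta$id)]
    records$region <- meta$region[match(records$id, meta$id)]
    records$site <- meta$site[match(records$id, meta$id)]
    aln <- codon_alignment(records, frame_offset = frame_offset)
  }
  sheet_tbl <- aln[c("id", "species", "region", "site")]

  qc <- stage("qc", screen_orf(aln))
  readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"), progress = FALSE)
  if (drop_failed_qc && any(!qc$pass)) {
    keep <- qc$id[qc$pass]
    aln <- codon_alignment(aln[aln$id %in% keep, ],
                           frame_offset = frame_offset)
    sheet_tbl <- sheet_tbl[sheet_tbl$id %in% keep, ]
  }

  set.seed(seed)
  div <- stage("diversity", diversity_summary(aln, sheet_tbl, min_n = min_n))
  readr::write_tsv(div, file.path(out_dir, "diversity_table.tsv"),
                   progress = FALSE)

  dem <- stage("demography",
               demography_summary(aln, sheet_tbl, min_n = min_n,
                                  reps = reps, seed = seed + 1L))
  readr::write_tsv(dem, file.path(out_dir, "demography_table.tsv"),
                   progress = FALSE)

  fst_rows <- list()
  networks <- list()
  for (sp in unique(sheet_tbl$species)) {
    sub <- sheet_tbl[sheet_tbl$species == sp, ]
    sizes <- table(sub$site)
    if (sum(sizes >= min_n) >= 2) {
      f <- stage("fst", {
        permutation_test(
          amova_fst(aln, sheet_tbl, species = sp, min_n = min_n),
          reps = reps, seed = seed + 2L)
      })
      fst_rows[[sp]] <- tidy(f)
    }
    net <- stage("network", {
      pop <- population_sample(aln, intersect(sub$id, aln$id), species = sp,
                               min_n = 1L)
      build_network(collapse_haplotypes(pop))
    })
    networks[[sp]] <- net
    write_graphml(net, file.path(out_dir, paste0(
      "network_", gsub("[^A-Za-z0-9]+", "_", sp), ".graphml")))
  }
  fst <- bind_rows(fst_rows)
  if (nrow(fst)) {
    readr::write_tsv(fst, file.path(out_dir, "fst_table.tsv"),
                     progress = FALSE)
  }

  log <- tibble(
    stage = c("seed", "reps", "min_n", "n_seq", "n_pass_qc"),
    value = as.character(c(seed, reps, min_n, nrow(qc), sum(qc$pass)))
  )
  readr::write_tsv(log, file.path(out_dir, "run_log.tsv"), progress = FALSE)
  invisible(list(qc = qc, diversity = div, demography = dem, fst = fst,
                 networks = networks,
                 paths = list(dir = out_dir), log = log))
}
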