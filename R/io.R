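# Tabular dialect used throughout: tab-separated, UTF-8, header row, "NA"
# for missing values.

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (empty, with a warning, for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a typed TSV table with schema validation
#'
#' @param path Path to a tab-separated file with a header row and `NA` for
#'   missing values.
#' @param required_columns Character vector of columns that must be present.
#' @param call_columns Columns (or `"*markers*"` for every non-structural
#'   column) whose values must be origin calls `P1`/`P2`/`HET`/`NA`;
#'   violations are reported with their line number.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, required_columns = character(0),
                           call_columns = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA", colClasses = "character")
  missing_cols <- setdiff(required_columns, names(tab))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (identical(call_columns, "*markers*")) {
    call_columns <- setdiff(names(tab), c("teliospore", "colony", "product"))
  }
  for (cc in intersect(call_columns, names(tab))) {
    bad <- which(!is.na(tab[[cc]]) & !(tab[[cc]] %in% c("P1", "P2", "HET")))
    if (length(bad)) {
      stop(sprintf("invalid call '%s' in column '%s' at line %d of %s",
                   tab[[cc]][bad[1L]], cc, bad[1L] + 1L, path), call. = FALSE)
    }
  }
  tab
}

#' Write a table in the package's TSV dialect
#'
#' @param table Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a marker map TSV
#'
#' Expects columns `scaffold`, `marker`, `position_kb`; positions must be
#' strictly increasing within a scaffold.
#'
#' @param path Path to the TSV.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  tab <- read_tsv_table(path, required_columns = c("scaffold", "marker", "position_kb"))
  marker_map(tab$scaffold, tab$marker, as.numeric(tab$position_kb))
}

# Polynomial rolling hash (mod 2^31 - 1) over a character representation;
# used only to fingerprint a run configuration in manifests.
config_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration, seed and a configuration fingerprint so that
#' any stochastic run can be reproduced exactly.
#'
#' @param dir Output directory (created if needed).
#' @param config A list of run parameters.
#' @param seed The seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   config = config,
                   config_hash = config_hash(list(config = config, seed = seed)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' In-study worked-example fixtures
#'
#' Builds the three small fixtures used as worked examples throughout the
#' package: (i) the eight-teliospore MAT-cohesion table (six teliospores with
#' receptor-HD cohesion maintained, of which one yielded both parental
#' mating types; one receptor-HD recombinant; one all-heterozygous diploid);
#' (ii) the mating-type panel for the new recombinant mating type and its
#' testers, whose pairwise crosses reproduce the published +/- pattern of
#' mycelium and teliospore formation; and (iii) the recombination-hotspot
#' example of seven haploid products with three recombinants across a 27-kb
#' interval (0.63 kb/cM). When `out_dir` is given the fixtures are also
#' written as TSV files.
#'
#' @param out_dir Optional directory to write `cohesion_progeny.tsv`,
#'   `mating_types.tsv`, `hotspot_progeny.tsv` and `hotspot_map.tsv` into.
#' @return A list with elements `cohesion` (progeny table), `mating_types`
#'   (data.frame of strains and their [mating_type()]s), `hotspot` (list with
#'   `progeny` and `map`).
#' @export
make_fixtures <- function(out_dir = NULL) {
  # (i) cohesion table: origin calls at the receptor (STE3) and HD markers,
  # three colonies per teliospore; T1 yields both parental classes, T7 a
  # receptor-HD recombinant, T8 a diploid.
  per_colony <- function(tid, calls) {
    data.frame(teliospore = tid,
               colony = sprintf("%s.%d", tid, seq_along(calls)),
               STE3 = vapply(calls, `[[`, "", 1L),
               HD = vapply(calls, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  p1 <- c("P1", "P1"); p2 <- c("P2", "P2")
  cohesion <- rbind(
    per_colony("T1", list(p1, p2, p1)),
    per_colony("T2", list(p2, p2, p2)),
    per_colony("T3", list(p1, p1, p1)),
    per_colony("T4", list(p1, p1, p1)),
    per_colony("T5", list(p2, p2, p2)),
    per_colony("T6", list(p1, p1, p1)),
    per_colony("T7", list(c("P1", "P2"), c("P1", "P2"), c("P1", "P2"))),
    per_colony("T8", list(c("HET", "HET"), c("HET", "HET"), c("HET", "HET")))
  )
  # (ii) mating-type panel: the recombinant product T7.1 carries the A1
  # receptor with the HD allele of the A2 parent; testers are the two
  # parents and a strain differing at both regions.
  mating_types <- data.frame(
    strain = c("T7.1", "ML2241", "CBS6832", "tester"),
    receptor = c("A1", "A1", "A2", "A2"),
    hd = c("A2-15", "A1-3", "A2-15", "A1-x"),
    stringsAsFactors = FALSE)
  # (iii) hotspot example: seven haploid products, markers 27 kb apart
  # flanking the HD1/HD2 pair, three recombinants.
  hotspot_map <- marker_map(scaffold = c("scaffold_7", "scaffold_7"),
                            marker = c("HSP70", "HD"),
                            position_kb = c(250, 277))
  hp <- data.frame(
    teliospore = sprintf("T%d", 1:7),
    colony = sprintf("T%d.1", 1:7),
    HD = c("P1", "P2", "P1", "P1", "P2", "P1", "P2"),
    HSP70 = c("P1", "P2", "P1", "P1", "P1", "P2", "P1"),
    stringsAsFactors = FALSE)
  fixtures <- list(cohesion = cohesion, mating_types = mating_types,
                   hotspot = list(progeny = hp, map = hotspot_map))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv_table(cohesion, file.path(out_dir, "cohesion_progeny.tsv"))
    write_tsv_table(mating_types, file.path(out_dir, "mating_types.tsv"))
    write_tsv_table(hp, file.path(out_dir, "hotspot_progeny.tsv"))
    write_tsv_table(as.data.frame(hotspot_map), file.path(out_dir, "hotspot_map.tsv"))
  }
  fixtures
}
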