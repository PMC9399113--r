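# Tabular readers/writers. All writers emit a `#`-prefixed provenance header
# (package version, timestamp-free content hash inputs: seed and scale tag
# where applicable) so downstream files are self-describing.

provenance_header <- function(what, extra = character()) {
  c(sprintf("# pgsfam %s: %s",
            as.character(utils::packageVersion("pgsfam")), what),
    if (length(extra)) paste0("# ", extra))
}

#' Write / read a TSV with a provenance header
#'
#' @param x data.frame.
#' @param path file path.
#' @param what one-line description for the header.
#' @param extra extra header lines (without the leading `#`).
#' @return `write_tsv_provenance()` returns `path` invisibly;
#'   `read_tsv_provenance()` returns a data.frame.
#' @export
write_tsv_provenance <- function(x, path, what = "table",
                                 extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(what, extra), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_provenance
#' @export
read_tsv_provenance <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write the person table of a cohort
#'
#' @param cohort a `family_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_person_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "family_cohort"))
  cols <- c("person_id", "family_id", "rearing_family_id", "role",
            "zygosity", "adopted", "subpop", "sex", "age", "y")
  write_tsv_provenance(
    cohort$persons[, cols], path, what = "person table",
    extra = sprintf("seed: %d", cohort$scenario$seed)
  )
}

#' Write a PLINK-raw-style additive dosage table
#'
#' One row per person, columns `person_id` then one dosage column per SNP
#' named `<snp>_<effect allele>` (additive coding 0/1/2).
#'
#' @param cohort a `family_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dosage_raw <- function(cohort, path) {
  stopifnot(inherits(cohort, "family_cohort"))
  d <- dosages(cohort)
  colnames(d) <- paste0(cohort$freqs$snp, "_", cohort$freqs$effect_allele)
  out <- data.frame(person_id = cohort$persons$person_id, d,
                    check.names = FALSE)
  write_tsv_provenance(out, path, what = "additive dosage matrix",
                       extra = sprintf("seed: %d", cohort$scenario$seed))
}

#' Read a weight table (TSV: snp, effect_allele, weight_cog, weight_noncog)
#'
#' @param path file path.
#' @return a weight table data.frame.
#' @export
read_weight_table <- function(path) {
  w <- read_tsv_provenance(path)
  need <- c("snp", "effect_allele", "weight_cog", "weight_noncog")
  if (!all(need %in% names(w))) {
    stop_param("weight table must have columns: ",
               paste(need, collapse = ", "))
  }
  if (!all(is.finite(w$weight_cog)) || !all(is.finite(w$weight_noncog))) {
    stop_param("weights must be finite")
  }
  w
}

#' Write a weight table
#'
#' @param weights weight table data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  write_tsv_provenance(weights, path, what = "PGS weight table")
}

#' Write a score table with its scale tag
#'
#' @param tab a score table (any standardization state).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  write_tsv_provenance(
    tab, path, what = "per-person polygenic score table",
    extra = sprintf("scale: %s", attr(tab, "scale") %||% "raw")
  )
}

#' Serialize an estimate set to JSON
#'
#' @param est an `estimate_set`.
#' @param path file path (`NULL` returns the JSON string).
#' @return the JSON string, invisibly when written to file.
#' @export
write_estimates_json <- function(est, path = NULL) {
  stopifnot(inherits(est, "estimate_set"))
  obj <- list(schema = "pgsfam-estimate-set-v1",
              design = est$design,
              n_persons = est$n_persons, n_families = est$n_families,
              coefficients = est$coefficients, derived = est$derived)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
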