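#' Keep only species-level taxa
#'
#' Taxa of lower taxonomic resolution (genus and above) are removed before
#' mapping, because higher-rank pan reconstructions would import metabolic
#' capabilities of species that are not actually present. Abundances are not
#' renormalized here: the coverage statistics need the pre-normalization
#' values.
#'
#' @param raw tibble: `sample_id` column plus one column per taxon, values
#'   relative abundances in `[0,1]`.
#' @param taxa tibble with columns `taxon` and `rank` (`"species"` or a
#'   higher rank); may also be supplied as a `"taxa"` attribute on `raw`.
#' @param threshold relative-abundance floor below which a taxon is ignored
#'   in richness counts (default 1e-6, i.e. 0.0001%).
#' @return the species-level table, with per-sample richness of named taxa
#'   recorded in attributes for the downstream mapping report.
#' @export
filter_species_level <- function(raw, taxa = attr(raw, "taxa"),
                                 threshold = 1e-6) {
  if (is.null(taxa)) {
    abort_gf("no taxon rank metadata (supply `taxa` or a 'taxa' attribute)",
             "input_error")
  }
  taxa <- tibble::as_tibble(taxa)
  taxon_cols <- setdiff(names(raw), "sample_id")
  if (!all(taxon_cols %in% taxa$taxon)) {
    abort_gf("taxa metadata does not cover all table columns", "input_error")
  }
  species <- taxa$taxon[taxa$rank == "species"]
  keep <- intersect(taxon_cols, species)

  amat <- as.matrix(raw[, taxon_cols, drop = FALSE])
  out <- raw[, c("sample_id", keep)]
  attr(out, "taxa") <- taxa[taxa$taxon %in% keep, ]
  attr(out, "richness_named") <- rowSums(amat > threshold)
  attr(out, "n_named_taxa") <- length(taxon_cols)
  out
}

#' Map species onto a reconstruction resource
#'
#' Matches species names against the resource by exact equality on a
#' canonicalized name (lowercase, punctuation runs collapsed to underscores)
#' and drops unmatched species. The mapping report carries the per-sample
#' coverage and richness statistics: coverage of named species reads,
#' coverage of resource-mapped reads (both relative to the raw, unfiltered
#' reads), the mapping coverage of species-level reads (mapped / species),
#' and richness counts at each stage. Taxa below the abundance floor are
#' excluded from richness and coverage counts. Samples in which no species
#' maps are flagged and excluded, with a warning.
#'
#' @param species_tbl output of [filter_species_level()].
#' @param resource_names character vector of species names available in the
#'   reconstruction resource.
#' @param threshold abundance floor, as in [filter_species_level()].
#' @return list with `table` (mapped, still unnormalized abundances) and
#'   `report` (a `mapping_report`).
#' @export
map_to_resource <- function(species_tbl, resource_names, threshold = 1e-6) {
  stopifnot(length(resource_names) > 0)
  species <- setdiff(names(species_tbl), "sample_id")
  mapped <- species[canonical_name(species) %in% canonical_name(resource_names)]

  smat <- as.matrix(species_tbl[, species, drop = FALSE])
  smat[smat <= threshold] <- 0
  mmat <- smat[, mapped, drop = FALSE]

  per_sample <- tibble::tibble(
    sample_id = species_tbl$sample_id,
    species_coverage = rowSums(smat),
    mapped_coverage = rowSums(mmat),
    mapped_of_species_reads = ifelse(rowSums(smat) > 0,
                                     rowSums(mmat) / rowSums(smat), NA_real_),
    richness_named = attr(species_tbl, "richness_named") %||%
      rep(NA_real_, nrow(species_tbl)),
    richness_species = rowSums(smat > threshold),
    richness_mapped = rowSums(mmat > threshold)
  )

  excluded <- per_sample$sample_id[per_sample$richness_mapped == 0]
  if (length(excluded)) {
    warn_gf(paste0("samples with no mapped species excluded: ",
                   paste(excluded, collapse = ", ")), "mapping_warning")
  }
  keep_rows <- !species_tbl$sample_id %in% excluded

  out <- species_tbl[keep_rows, c("sample_id", mapped)]
  attr(out, "taxa") <- tibble::tibble(taxon = mapped, rank = "species")

  report <- structure(list(
    per_sample = per_sample,
    excluded_samples = excluded,
    totals = tibble::tibble(
      n_named_taxa = attr(species_tbl, "n_named_taxa") %||% NA_integer_,
      n_named_species = length(species),
      n_mapped_species = length(mapped)
    )
  ), class = "mapping_report")
  list(table = out, report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  with(x$totals, cat(sprintf(
    "<mapping_report> %s named taxa; %d named species; %d mapped species\n",
    format(n_named_taxa), n_named_species, n_mapped_species)))
  cat(sprintf("  mean read coverage of named species: %.1f%%\n",
              100 * mean(x$per_sample$species_coverage)))
  cat(sprintf("  mean read coverage of mapped species: %.1f%%\n",
              100 * mean(x$per_sample$mapped_coverage)))
  cat(sprintf("  mean mapping coverage of species-level reads: %.1f%%\n",
              100 * mean(x$per_sample$mapped_of_species_reads, na.rm = TRUE)))
  if (length(x$excluded_samples))
    cat("  excluded samples:", paste(x$excluded_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mapping_report <- function(x, ...) x$per_sample

#' @export
glance.mapping_report <- function(x, ...) {
  dplyr::bind_cols(
    x$totals,
    tibble::tibble(
      mean_species_coverage = mean(x$per_sample$species_coverage),
      mean_mapped_coverage = mean(x$per_sample$mapped_coverage),
      mean_mapping_of_species_reads =
        mean(x$per_sample$mapped_of_species_reads, na.rm = TRUE),
      mean_richness_species = mean(x$per_sample$richness_species),
      mean_richness_mapped = mean(x$per_sample$richness_mapped),
      n_excluded_samples = length(x$excluded_samples)
    )
  )
}

#' Renormalize relative abundances with an abundance floor
#'
#' Two-pass: rows are first scaled to sum to one, entries below `threshold`
#' (default 1e-6, the 0.0001% floor) are then set to zero, and rows are
#' scaled to one again. The result feeds community-model construction.
#' Samples whose row sums to zero are flagged and excluded with a warning.
#' The operation is idempotent.
#'
#' @param table tibble: `sample_id` plus taxon columns, values >= 0.
#' @param threshold abundance floor applied after the first normalization.
#' @return the renormalized table (rows summing to one within 1e-9).
#' @export
renormalize_abundances <- function(table, threshold = 1e-6) {
  cols <- setdiff(names(table), "sample_id")
  amat <- as.matrix(table[, cols, drop = FALSE])
  if (any(amat < 0)) abort_gf("negative abundances", "input_error")

  rs <- rowSums(amat)
  zero_rows <- rs == 0
  if (any(zero_rows)) {
    warn_gf(paste0("all-zero abundance rows excluded: ",
                   paste(table$sample_id[zero_rows], collapse = ", ")),
            "abundance_warning")
    amat <- amat[!zero_rows, , drop = FALSE]
    table <- table[!zero_rows, ]
    rs <- rs[!zero_rows]
  }
  amat <- amat / rs
  amat[amat < threshold] <- 0
  rs2 <- rowSums(amat)
  if (any(rs2 == 0)) {
    bad <- table$sample_id[rs2 == 0]
    warn_gf(paste0("rows losing all taxa at the abundance floor excluded: ",
                   paste(bad, collapse = ", ")), "abundance_warning")
    amat <- amat[rs2 > 0, , drop = FALSE]
    table <- table[rs2 > 0, ]
    rs2 <- rs2[rs2 > 0]
  }
  amat <- amat / rs2
  out <- dplyr::bind_cols(table["sample_id"], tibble::as_tibble(amat))
  attr(out, "taxa") <- attr(table, "taxa")
  out
}
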