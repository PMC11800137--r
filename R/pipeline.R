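#' Prioritize candidate variants in a dominant pedigree
#'
#' The main entry point: reads a multi-sample VCF, a 6-column PED pedigree
#' and a per-variant annotation table; normalizes and joins them by variant
#' key; applies the candidate cascade (protein-impact consequence,
#' population rarity, dominant co-segregation); scores the survivors against
#' a registry of in-silico predictor criteria; and ranks them by cumulative
#' damaging score. Deterministic given its inputs.
#'
#' @param vcf path to a VCF file, or a `variant_set` from [read_vcf()].
#' @param ped path to a PED file, or a [pedigree()].
#' @param annotations path to an annotation TSV, an `annotation_table` from
#'   [read_annotation_table()], or `NULL` for no annotations.
#' @param config a [filter_config()], or a path to a JSON/YAML file for
#'   [read_filter_config()].
#' @param criteria a [criteria_set()], or a path for [read_criteria()];
#'   default [default_criteria()].
#' @return An object of class `prioritization_report`: list with
#'   \describe{
#'     \item{ranked}{data frame of surviving variants sorted by rank, with
#'       key fields, frequencies, segregation counts, score,
#'       `n_tools_deleterious` and per-tool verdict columns.}
#'     \item{funnel}{per-stage filter counts.}
#'     \item{known_gene_hits}{annotation rows in the configured known genes
#'       (reported, never excluded).}
#'     \item{config, criteria, n_input, samples, version}{run provenance.}
#'   }
#' @examples
#' extdata <- system.file("extdata", package = "pedprio")
#' rep <- prioritize_variants(
#'   vcf = file.path(extdata, "candidates7_synthetic.vcf"),
#'   ped = file.path(extdata, "family_wgs7.ped"),
#'   annotations = file.path(extdata, "candidates7_synthetic.tsv"),
#'   criteria = file.path(extdata, "criteria20_synthetic.json")
#' )
#' rep
#' @export
prioritize_variants <- function(vcf, ped, annotations = NULL,
                                config = filter_config(),
                                criteria = default_criteria()) {
  vset <- if (inherits(vcf, "variant_set")) vcf else read_vcf(vcf)
  ped <- if (inherits(ped, "pedigree")) ped else read_ped(ped)
  ann <- if (is.null(annotations) || inherits(annotations, "annotation_table"))
    annotations else read_annotation_table(annotations)
  cfg <- if (inherits(config, "filter_config")) config
         else read_filter_config(config)
  cs <- if (inherits(criteria, "criteria_set")) criteria
        else read_criteria(criteria)

  if (nrow(vset$variants) > 0L) {
    shared <- intersect(vset$samples, ped$individual_id)
    if (!length(shared)) {
      stop("no overlapping sample ids between VCF (",
           paste(utils::head(vset$samples, 3L), collapse = ", "),
           ", ...) and pedigree")
    }
  }
  joined <- join_annotations(vset, ann)
  screen <- known_gene_screen(joined, cfg)
  casc <- apply_cascade(joined, vset$geno, ped, cfg)
  scored <- score_variants(casc$survivors, cs)
  ranked <- rank_variants(scored)
  if (nrow(ranked)) {
    ranked$n_carriers <- vapply(casc$survivor_idx[order_of(ranked, casc)],
                                function(i) count_carriers(vset$geno[i, ]),
                                integer(1))
  } else {
    ranked$n_carriers <- integer(0)
  }
  structure(list(ranked = ranked,
                 funnel = casc$funnel,
                 known_gene_hits = screen,
                 config = cfg,
                 criteria = cs,
                 n_input = nrow(vset$variants),
                 samples = vset$samples,
                 version = as.character(utils::packageVersion("pedprio"))),
            class = "prioritization_report")
}

# map ranked rows back to cascade survivor indices via the variant key
order_of <- function(ranked, casc) {
  match(ranked$key, casc$survivors$key)
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("Variant prioritization report (pedprio", x$version, ")\n")
  cat(sprintf("  %d input record(s), %d sample(s), %d candidate(s) after cascade\n",
              x$n_input, length(x$samples), nrow(x$ranked)))
  cat("  Filter funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("    %-12s in %5d  pass %5d  fail %5d\n",
                x$funnel$stage[i], x$funnel$n_in[i],
                x$funnel$n_pass[i], x$funnel$n_fail[i]))
  }
  if (nrow(x$known_gene_hits)) {
    cat("  Known-gene screen: ", nrow(x$known_gene_hits), " hit(s) in ",
        paste(unique(x$known_gene_hits$gene), collapse = ", "), "\n", sep = "")
  } else {
    cat("  Known-gene screen: no hits\n")
  }
  if (nrow(x$ranked)) {
    cols <- intersect(c("rank", "key", "gene", "hgvs_p", "score",
                        "n_tools_deleterious", "n_violations"),
                      names(x$ranked))
    cat("  Top candidates:\n")
    print(utils::head(x$ranked[, cols, drop = FALSE], 10L))
  }
  invisible(x)
}

#' @export
summary.prioritization_report <- function(object, ...) {
  cat("Candidates:", nrow(object$ranked), "of", object$n_input,
      "input records; max attainable score",
      attr(object$criteria, "max_score"), "\n")
  if (nrow(object$ranked)) {
    top <- object$ranked[1L, ]
    cat("Top-ranked:", top$key,
        if (!is.null(top$gene) && !is.na(top$gene)) paste0("(", top$gene, ")") else "",
        "score", top$score, "with", top$n_tools_deleterious,
        "criteria satisfied\n")
  }
  invisible(object)
}

#' Write a prioritization report to TSV or JSON
#'
#' TSV emits the ranked table with a stable, documented column order (key
#' fields, frequencies, segregation counts, score columns, per-tool
#' verdicts). JSON emits the whole report (ranked table, funnel, known-gene
#' hits, config echo, version) and round-trips through [read_report()].
#' Output contains no timestamps: identical reports give byte-identical
#' files.
#'
#' @param report a `prioritization_report`.
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- intersect(c("rank", "key", "chrom", "pos", "ref", "alt", "gene",
                         "hgvs_c", "hgvs_p", "consequence",
                         "ExAC_AF", "gnomAD_AF", "KG1000_AF", "maf_flagged",
                         "n_informative", "n_consistent", "n_violations",
                         "segregates", "n_carriers", "score",
                         "n_tools_deleterious"),
                       names(report$ranked))
    out <- report$ranked[, c(first, setdiff(names(report$ranked), first)),
                         drop = FALSE]
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  } else {
    payload <- list(
      ranked = report$ranked,
      funnel = report$funnel,
      known_gene_hits = report$known_gene_hits,
      config = unclass(report$config),
      n_input = report$n_input,
      samples = report$samples,
      version = report$version
    )
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(file)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param file path to the JSON file.
#' @return List with the report components (`ranked`, `funnel`,
#'   `known_gene_hits`, `config`, `n_input`, `samples`, `version`).
#' @export
read_report <- function(file) {
  jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
}
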