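#' Read a multi-sample VCF into a variant set
#'
#' Reads VCF 4.x via \pkg{vcfR}, splits multi-allelic sites so that every
#' ALT allele of every site becomes one biallelic record, converts GT fields
#' to alternate-allele counts (`0/1` -> 1, `1/1` -> 2, `0/0` -> 0, `./.` ->
#' missing; phased `|` treated as unphased), and normalizes indels to their
#' minimal representation.
#'
#' @param file path to a `.vcf` (or `.vcf.gz`) file.
#' @return An object of class `variant_set`: list with
#'   \describe{
#'     \item{variants}{data frame with `chrom`, `pos`, `ref`, `alt`, `key`.}
#'     \item{geno}{integer matrix, one row per record, one column per sample;
#'       entries are alternate-allele counts, `NA` missing.}
#'     \item{samples}{sample ids from the VCF header.}
#'   }
#' @seealso [normalize_variant()], [variant_key()], [write_vcf()]
#' @export
read_vcf <- function(file) {
  v <- tryCatch(
    vcfR::read.vcfR(file, verbose = FALSE),
    error = function(e) stop("malformed VCF '", file, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  samples <- colnames(v@gt)[-1L]
  if (n_site == 0L) {
    return(new_variant_set(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE),
      matrix(integer(), nrow = 0L, ncol = length(samples),
             dimnames = list(NULL, samples))
    ))
  }
  fmt <- v@gt[, 1L]
  if (any(!vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    stop("VCF is missing the GT genotype field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_site,
                                     dimnames = list(NULL, samples))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rows <- list(); genos <- list(); k <- 0L
  for (i in seq_len(n_site)) {
    alleles <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/", fixed = TRUE)
    for (j in seq_along(alts[[i]])) {
      k <- k + 1L
      cnt <- vapply(alleles, function(a) {
        if (any(a == "." | is.na(a))) return(NA_integer_)
        sum(a == as.character(j))
      }, integer(1))
      rows[[k]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[[i]][j], stringsAsFactors = FALSE
      )
      genos[[k]] <- cnt
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  norm <- normalize_variant(variants)
  new_variant_set(norm, geno)
}

new_variant_set <- function(variants, geno) {
  variants$key <- variant_key(variants)
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "biallelic record(s),",
      length(x$samples), "sample(s)\n")
  if (nrow(x$variants)) print(utils::head(x$variants, 10L))
  invisible(x)
}

#' Minimal representation of a variant
#'
#' Trims the shared suffix, then the shared prefix (advancing `pos`), always
#' retaining at least one base of REF and ALT, so each allele pair is reduced
#' to its minimal form with an anchor base. SNVs are unchanged and the
#' operation is idempotent. Left-alignment through repetitive flanking
#' sequence would additionally require the reference genome, which this
#' pipeline deliberately does not load; upstream callers emitting
#' GATK-normalized VCFs already satisfy it.
#'
#' @param chrom data frame with columns `pos`, `ref`, `alt` (extra columns
#'   are preserved), or a chromosome vector when `pos`, `ref`, `alt` are
#'   given separately.
#' @param pos,ref,alt vectors, used when `chrom` is not a data frame.
#' @return Same shape as the input with `pos`, `ref`, `alt` normalized.
#' @examples
#' normalize_variant("4", 100, "CAA", "CA")  # -> pos 100, ref "CA", alt "C"
#' @export
normalize_variant <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
  } else {
    df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    r <- df$ref[i]; a <- df$alt[i]; p <- df$pos[i]
    # shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # shared prefix, keeping an anchor base
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    df$ref[i] <- r; df$alt[i] <- a; df$pos[i] <- p
  }
  if (is.data.frame(chrom)) df else df
}

#' Canonical variant key
#'
#' `"chrom:pos:ref:alt"` for a normalized record; equal keys identify equal
#' normalized variants and drive the annotation join.
#'
#' @inheritParams normalize_variant
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    with(chrom, paste(chrom, pos, ref, alt, sep = ":"))
  } else {
    paste(chrom, pos, ref, alt, sep = ":")
  }
}

#' Write a variant set to a plain-text VCF 4.2 file
#'
#' Emits one biallelic record per row with GT-only genotype columns
#' (`0/0`, `0/1`, `1/1`, `./.`). Output is uncompressed, deterministic text:
#' two writes of the same object are byte-identical.
#'
#' @param vset a `variant_set` (see [read_vcf()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(vset, file) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vset$geno + 1L],
                   nrow = nrow(vset$variants))
  gt_str[is.na(gt_str)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vset$samples), collapse = "\t")
  )
  body <- if (nrow(vset$variants)) {
    paste(vset$variants$chrom, vset$variants$pos, ".", vset$variants$ref,
          vset$variants$alt, ".", "PASS", ".", "GT",
          apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a per-variant annotation table
#'
#' Reads a TSV with header whose key columns are `chrom`, `pos`, `ref`,
#' `alt`; all other columns are annotations: population allele frequencies,
#' in-silico predictor values (numeric or categorical), `gene`,
#' `consequence`, HGVS fields, and anything else (preserved as opaque
#' columns). `"."` and empty cells are missing. Keys are normalized (see
#' [normalize_variant()]) and must be unique.
#'
#' @param file path to the TSV, or a character vector of its lines.
#' @return An object of class `annotation_table`: data frame keyed by `key`
#'   with one row per variant.
#' @examples
#' tsv <- system.file("extdata", "candidates7_synthetic.tsv", package = "pedprio")
#' ann <- read_annotation_table(tsv)
#' ann[, c("key", "gene", "consequence")]
#' @export
read_annotation_table <- function(file) {
  df <- utils::read.delim(if (length(file) > 1L) textConnection(file) else file,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation table is missing key column(s): ",
         paste(miss, collapse = ", "))
  }
  df[df == "." | df == ""] <- NA
  df$pos <- as.integer(df$pos)
  # type the annotation columns: numeric when every non-missing value parses;
  # a column mixing parseable and unparseable values is malformed
  for (col in setdiff(names(df), need)) {
    vals <- df[[col]]
    num <- suppressWarnings(as.numeric(vals))
    parses <- !is.na(num)
    present <- !is.na(vals)
    if (any(parses)) {
      if (any(present & !parses)) {
        bad <- which(present & !parses)[1L]
        stop("non-numeric value '", vals[bad], "' in numeric column '",
             col, "' (row ", bad, ")")
      }
      df[[col]] <- num
    }
  }
  df <- normalize_variant(df)
  df$key <- variant_key(df)
  if (anyDuplicated(df$key)) {
    stop("duplicate variant key(s) in annotation table: ",
         paste(unique(df$key[duplicated(df$key)]), collapse = ", "))
  }
  df <- df[, c("key", setdiff(names(df), "key"))]
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Join annotations onto a variant set by normalized key
#'
#' Records with no matching annotation row get an all-missing profile (never
#' an error): sparse annotation must not drop variants before filtering.
#'
#' @param vset a `variant_set`.
#' @param ann an `annotation_table`, or `NULL` for no annotations.
#' @return Data frame with one row per variant-set record: the key columns
#'   plus every annotation column (NA where unmatched).
#' @export
join_annotations <- function(vset, ann = NULL) {
  base <- vset$variants
  if (is.null(ann)) return(base)
  idx <- match(base$key, ann$key)
  extra <- ann[idx, setdiff(names(ann), names(base)), drop = FALSE]
  rownames(extra) <- NULL
  cbind(base, extra)
}
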