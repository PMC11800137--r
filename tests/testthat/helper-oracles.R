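# Independent oracles and fixture builders. Everything here re-derives the
# expected behaviour by a different route than the package code (explicit
# per-individual loops, exhaustive enumeration, transmission-probability
# sums) so the two implementations can be compared.

extdata <- function(f) system.file("extdata", f, package = "pedprio")

ped_wgs7 <- function() read_ped(extdata("family_wgs7.ped"))

# Table-style genotype map: five affected het carriers, two unaffected
# non-carriers.
geno_wgs7 <- function() {
  c("II-1" = 1, "III-2" = 1, "III-3" = 1, "III-4" = 1, "III-5" = 1,
    "II-2" = 0, "III-8" = 0)
}

# --- co-segregation oracle: literal per-individual loop ---------------------

oracle_coseg <- function(ped, genotypes, min_informative = 2L) {
  n_inf <- 0L; n_con <- 0L; viol <- character(0)
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    aff <- ped$affection[i]
    g <- if (id %in% names(genotypes)) genotypes[[id]] else NA
    if (aff == "unknown" || is.na(g)) next
    n_inf <- n_inf + 1L
    carrier <- g >= 1
    ok <- if (aff == "affected") carrier else !carrier
    if (ok) n_con <- n_con + 1L else viol <- c(viol, id)
  }
  list(n_informative = n_inf, n_consistent = n_con,
       n_violations = length(viol), violating_ids = viol,
       segregates = length(viol) == 0L && n_inf >= min_informative)
}

# --- damaging-score oracle: independent per-criterion re-evaluation ---------

oracle_score <- function(profile, cs) {
  total <- 0; n_del <- 0L
  for (cr in cs) {
    val <- profile[[cr$tool]]
    if (is.null(val) || length(val) == 0L || is.na(val)) next
    sat <- if (cr$kind == "label_in") {
      as.character(val) %in% cr$damaging_labels
    } else if (cr$kind == "numeric_below") {
      as.numeric(val) < cr$threshold
    } else {
      as.numeric(val) > cr$threshold
    }
    if (sat) { total <- total + cr$weight; n_del <- n_del + 1L }
  }
  list(score = total, n_tools_deleterious = n_del)
}

# Random profile over a registry: numeric tools get values across the whole
# scale (including exact boundary values), label tools draw from damaging
# and non-damaging labels, and every entry may be missing.
random_profile <- function(cs, p_missing = 0.2) {
  prof <- list()
  for (cr in cs) {
    if (stats::runif(1) < p_missing) {
      prof[[cr$tool]] <- NA
    } else if (cr$kind == "label_in") {
      prof[[cr$tool]] <- sample(c(cr$damaging_labels, "N", "T", "benign"), 1L)
    } else {
      prof[[cr$tool]] <- sample(c(cr$threshold,  # boundary: must not satisfy
                                  cr$threshold + stats::runif(1, 0, 5),
                                  cr$threshold - stats::runif(1, 0, 5)), 1L)
    }
  }
  prof
}

# --- minimal-representation oracle: character-vector trim ------------------

oracle_normalize <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# --- Mendelian trio consistency --------------------------------------------

# alleles a parent of count g can transmit
transmissible <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)

mendelian_ok <- function(ped, genotypes) {
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    child <- genotypes[[ped$individual_id[i]]]
    if (is.na(child)) next
    fa_g <- if (is.na(fa)) NA else genotypes[[fa]]
    mo_g <- if (is.na(mo)) NA else genotypes[[mo]]
    fa_all <- if (is.na(fa) || is.na(fa_g)) 0:1 else transmissible(fa_g)
    mo_all <- if (is.na(mo) || is.na(mo_g)) 0:1 else transmissible(mo_g)
    possible <- unique(outer(fa_all, mo_all, `+`))
    if (!(child %in% possible)) return(FALSE)
  }
  TRUE
}

# --- exact segregation probability by full enumeration ---------------------

# P(cosegregation_check segregates) for a variant of founder allele
# frequency q gene-dropped through `ped`, with the given fixed affection
# vector, genotypes observed on `subset` only. Enumerates all 3^n member
# genotype assignments; joint probability is the product of founder
# Hardy-Weinberg terms and Mendelian transmission terms.
transmission_prob <- function(child, fa, mo) {
  # P(child count | parent counts): each parent passes an alt allele with
  # probability count/2
  pf <- fa / 2; pm <- mo / 2
  switch(as.character(child),
    "0" = (1 - pf) * (1 - pm),
    "1" = pf * (1 - pm) + (1 - pf) * pm,
    "2" = pf * pm)
}

exact_seg_prob <- function(ped, q, subset, min_informative = 2L) {
  n <- nrow(ped)
  ids <- ped$individual_id
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    p <- 1
    for (i in seq_len(n)) {
      p <- p * if (founder[i]) hwe[g[i] + 1L] else
        transmission_prob(g[i], g[match(ped$father_id[i], ids)],
                          g[match(ped$mother_id[i], ids)])
      if (p == 0) break
    }
    if (p == 0) next
    obs <- setNames(g, ids)[subset]
    if (oracle_coseg(ped, obs, min_informative)$segregates) total <- total + p
  }
  total
}

# small nuclear pedigree used by enumeration tests: 2 founders, 4 children
ped_nuclear6 <- function(affection = c("affected", "unaffected", "affected",
                                       "affected", "unaffected", "unknown")) {
  pedigree(
    individual_id = c("F", "M", "C1", "C2", "C3", "C4"),
    father_id = c(NA, NA, "F", "F", "F", "F"),
    mother_id = c(NA, NA, "M", "M", "M", "M"),
    sex = c("male", "female", "male", "female", "male", "female"),
    affection = affection
  )
}

# write a VCF from raw lines and read it back
read_vcf_lines <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  on.exit(unlink(f))
  read_vcf(f)
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
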