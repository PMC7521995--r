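#' Read a PRS SNP-weight table
#'
#' A weight table defines a polygenic risk score: one row per SNP with its
#' effect allele, the other allele, and the per-effect-allele log-odds-ratio
#' weight.  Published breast-cancer PRS use 313 SNPs; the epithelial ovarian
#' cancer scores use 30 (all-EOC) and 22 (high-grade serous) SNPs.
#'
#' The file is tab-separated with a header.  `dialect` maps the canonical
#' field names to the column names actually present, so supplementary-table
#' layouts with different headers can be read without editing the file.
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping canonical names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `weight`, and optionally `effect_allele_frequency`) to
#'   the file's column names.  Defaults to the canonical names themselves.
#' @return An object of class `prs_weight_table`: a data frame with the
#'   canonical columns (frequency column present only when supplied).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\tchromosome\tposition\teffect_allele\tother_allele\tweight",
#'              "rs1\t1\t1000\tA\tG\t0.05"), tf)
#' read_weight_table(tf)
#' @export
read_weight_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  canonical <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "weight")
  map <- stats::setNames(c(canonical, "effect_allele_frequency"),
                         c(canonical, "effect_allele_frequency"))
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), names(map))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    map[names(dialect)] <- dialect
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#")
  miss <- canonical[!map[canonical] %in% names(raw)]
  if (length(miss))
    stop("weight table missing required column(s): ",
         paste(sprintf("%s (expected as '%s')", miss, map[miss]), collapse = ", "))
  tab <- data.frame(
    variant_id    = raw[[map["variant_id"]]],
    chromosome    = raw[[map["chromosome"]]],
    position      = as.integer(raw[[map["position"]]]),
    effect_allele = toupper(raw[[map["effect_allele"]]]),
    other_allele  = toupper(raw[[map["other_allele"]]]),
    weight        = as.numeric(raw[[map["weight"]]]),
    stringsAsFactors = FALSE
  )
  if (map["effect_allele_frequency"] %in% names(raw))
    tab$effect_allele_frequency <- as.numeric(raw[[map["effect_allele_frequency"]]])
  validate_weight_table(tab)
}

#' Construct/validate a PRS weight table from a data frame
#'
#' @param tab Data frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `weight`, and optionally
#'   `effect_allele_frequency`.
#' @return A validated `prs_weight_table`.
#' @export
validate_weight_table <- function(tab) {
  if (nrow(tab) == 0L) stop("weight table is empty: a PRS needs at least one SNP")
  if (anyDuplicated(tab$variant_id))
    stop("duplicate variant_id in weight table: ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]), collapse = ", "))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  if (any(!ok_allele(tab$effect_allele)) || any(!ok_allele(tab$other_allele)))
    stop("alleles must be single bases A/C/G/T")
  if (any(tab$effect_allele == tab$other_allele))
    stop("effect_allele must differ from other_allele (offending: ",
         paste(tab$variant_id[tab$effect_allele == tab$other_allele], collapse = ", "), ")")
  if (any(!is.finite(tab$weight))) stop("weights must be finite")
  if (!is.null(tab$effect_allele_frequency)) {
    f <- tab$effect_allele_frequency
    if (any(!is.na(f) & (f <= 0 | f >= 1)))
      stop("effect_allele_frequency must lie in (0,1)")
  }
  rownames(tab) <- NULL
  class(tab) <- c("prs_weight_table", "data.frame")
  tab
}

#' Construct a dosage matrix
#'
#' Effect-allele dosages per carrier: a carriers-by-variants matrix with
#' values in `[0, 2]` (`NA` allowed for missing genotypes).  `effect_allele`
#' and `other_allele`, when supplied, record which allele each column counts,
#' enabling harmonisation against a weight table.
#'
#' @param dosages Numeric matrix (carriers in rows, variants in columns).
#' @param carrier_ids,variant_ids Row/column identifiers (defaults taken from
#'   dimnames).
#' @param effect_allele,other_allele Optional per-variant allele labels for
#'   the counted allele and its partner.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, carrier_ids = rownames(dosages),
                          variant_ids = colnames(dosages),
                          effect_allele = NULL, other_allele = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(carrier_ids)) carrier_ids <- as.character(seq_len(nrow(dosages)))
  if (is.null(variant_ids)) stop("variant_ids are required")
  if (length(carrier_ids) != nrow(dosages) || length(variant_ids) != ncol(dosages))
    stop("id lengths do not match the dosage matrix dimensions")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  if (!is.null(effect_allele) && length(effect_allele) != ncol(dosages))
    stop("effect_allele must have one entry per variant")
  dimnames(dosages) <- list(as.character(carrier_ids), as.character(variant_ids))
  structure(list(dosages = dosages,
                 carrier_ids = as.character(carrier_ids),
                 variant_ids = as.character(variant_ids),
                 effect_allele = if (is.null(effect_allele)) NULL else toupper(effect_allele),
                 other_allele = if (is.null(other_allele)) NULL else toupper(other_allele)),
            class = "dosage_matrix")
}

#' Read a dosage matrix from a delimited file
#'
#' Plain TSV layout: first column carrier id, remaining columns one variant
#' each (header row holds variant ids); empty cells are missing.
#'
#' @param path Path to the TSV file.
#' @return A [dosage_matrix()] without allele labels (assumed already
#'   oriented to the weight table's effect alleles).
#' @export
read_dosage_matrix <- function(path) {
  if (!file.exists(path)) stop("dosage file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (ncol(df) < 2L) stop("dosage file needs a carrier-id column plus >=1 variant")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dosage_matrix(m, carrier_ids = as.character(df[[1L]]),
                variant_ids = colnames(df)[-1L])
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts a per-genotype dosage FORMAT field (default `DS`) and labels each
#' variant with REF/ALT so that [harmonize_dosages()] can orient columns to a
#' weight table.  The ALT allele is taken as the counted (dosage) allele, the
#' VCF convention for imputed dosages.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param field FORMAT field holding the dosage (default `"DS"`).
#' @return A [dosage_matrix()] with allele labels.
#' @export
read_dosage_vcf <- function(path, field = "DS") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = field, as.numeric = TRUE)
  if (all(is.na(ds))) stop("no '", field, "' FORMAT field found in ", path)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dosage_matrix(t(ds), carrier_ids = colnames(ds), variant_ids = ids,
                effect_allele = fix[, "ALT"], other_allele = fix[, "REF"])
}

#' Orient dosage columns to a weight table's effect alleles
#'
#' For each shared variant: if the dosage matrix counts the weight table's
#' effect allele, the column is kept; if the alleles are swapped, the dosage
#' is flipped to `2 - g`; any other allele pair is an error.
#' Strand-ambiguous SNPs (A/T or C/G) are matched by allele labels only and
#' reported with a warning, since strand cannot be resolved from labels.
#'
#' @param dosages A [dosage_matrix()] with allele labels.
#' @param weights A `prs_weight_table`.
#' @return A [dosage_matrix()] whose shared columns count the weight table's
#'   effect allele.
#' @export
harmonize_dosages <- function(dosages, weights) {
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(weights, "prs_weight_table"))
  if (is.null(dosages$effect_allele))
    stop("dosage matrix carries no allele labels; nothing to harmonize")
  shared <- intersect(dosages$variant_ids, weights$variant_id)
  if (!length(shared)) stop("no shared variants between dosages and weight table")
  wt <- weights[match(shared, weights$variant_id), ]
  j <- match(shared, dosages$variant_ids)
  d_eff <- dosages$effect_allele[j]
  d_oth <- dosages$other_allele[j]
  same <- d_eff == wt$effect_allele & (is.na(d_oth) | d_oth == wt$other_allele)
  swap <- d_eff == wt$other_allele & (is.na(d_oth) | d_oth == wt$effect_allele)
  bad <- !(same | swap)
  if (any(bad))
    stop("allele mismatch for variant(s): ", paste(shared[bad], collapse = ", "))
  ambiguous <- paste0(pmin(wt$effect_allele, wt$other_allele),
                      pmax(wt$effect_allele, wt$other_allele)) %in% c("AT", "CG")
  if (any(ambiguous))
    warning("strand-ambiguous SNP(s) matched by allele labels only: ",
            paste(shared[ambiguous], collapse = ", "))
  m <- dosages$dosages
  flip <- j[swap]
  m[, flip] <- 2 - m[, flip]
  eff <- dosages$effect_allele; oth <- dosages$other_allele
  eff[j] <- wt$effect_allele
  if (!is.null(oth)) oth[j] <- wt$other_allele
  dosage_matrix(m, dosages$carrier_ids, dosages$variant_ids,
                effect_allele = eff, other_allele = oth)
}
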