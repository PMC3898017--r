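#' Read a gene annotation (GFF3 or TSV)
#'
#' Returns one row per gene with 1-based inclusive coordinates, sorted by
#' `(replicon, start)`.  The TSV dialect expects a header with columns
#' `gene_id`, `replicon`, `start`, `end`, `strand` and optionally `product`
#' and `category`; GFF3 gene identifiers are taken from the `ID` (or
#' `locus_tag`/`Name`) attribute.  Genes without a functional category get
#' the default category `"hypothetical"`.  Overlapping genes are retained
#' as-is.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param feature_type for GFF3, which feature type to keep (default
#'   `"gene"`; all features kept if none match).
#' @return data.frame with columns `gene_id`, `replicon`, `start`, `end`,
#'   `strand`, `product`, `category`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "tsv"),
                            feature_type = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) && "type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == feature_type))
      gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
    mc <- S4Vectors::mcols(gr)
    pick <- function(cols) {
      for (cl in cols) if (cl %in% names(mc)) {
        v <- as.character(mc[[cl]])
        if (!all(is.na(v))) return(v)
      }
      rep(NA_character_, length(gr))
    }
    ids <- pick(c("ID", "locus_tag", "Name", "gene_id"))
    if (anyNA(ids)) ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
    ann <- data.frame(
      gene_id  = ids,
      replicon = as.character(GenomicRanges::seqnames(gr)),
      start    = GenomicRanges::start(gr),
      end      = GenomicRanges::end(gr),
      strand   = as.character(GenomicRanges::strand(gr)),
      product  = pick(c("product", "description", "Note")),
      category = pick("category"),
      stringsAsFactors = FALSE)
  } else {
    ann <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "replicon", "start", "end", "strand")
    miss <- setdiff(need, names(ann))
    if (length(miss)) stop("TSV annotation lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (!"product" %in% names(ann)) ann$product <- NA_character_
    if (!"category" %in% names(ann)) ann$category <- NA_character_
    ann <- ann[c(need, "product", "category")]
  }
  validate_genes(ann)
}

validate_genes <- function(ann) {
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (any(ann$start < 1)) stop("gene start below 1")
  if (any(ann$start > ann$end)) stop("gene with start > end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(ann$strand, c("+", "-"))), collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  ann$product[is.na(ann$product)] <- ""
  ann$category[is.na(ann$category) | ann$category == ""] <- "hypothetical"
  ann <- ann[order(ann$replicon, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write gene models as GFF3
#'
#' @param genes gene data.frame (as from [read_annotation()]).
#' @param path output file.
#' @param genome optional [Genome] supplying sequence lengths for the header.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path, genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$product <- genes$product
  S4Vectors::mcols(gr)$category <- genes$category
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <-
      genome$lengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
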