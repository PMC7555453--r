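.CALL_SPECIES <- c("pork", "chicken", "beef")

#' The PCR assay panel
#'
#' Loads the packaged multiplex-assay panel: the endpoint multiplex on
#' mitochondrial cytochrome b (universal forward primer plus species
#' reverse primers; amplicons 274/398/169/439 bp for beef, pork,
#' chicken-turkey and horse) and the real-time multiplexes on single-copy
#' genomic targets (104 bp beef phosphodiesterase, 107 bp pork beta-actin,
#' 97 bp mammal/poultry myostatin, 135 bp chicken interleukin-2), with
#' their fluorophores. Amplicon lengths are validated on load.
#'
#' @param file Optional path to a panel CSV (defaults to the packaged one).
#' @return \code{data.frame} with columns \code{species_scope},
#'   \code{assay}, \code{target_gene}, \code{primer_name},
#'   \code{amplicon_bp}, \code{fluorophore}.
#' @export
assayPanel <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "table2_panel.csv", package = "tagprint",
                        mustWork = TRUE)
  panel <- utils::read.csv(file, stringsAsFactors = FALSE)
  mt <- sort(panel$amplicon_bp[panel$assay == "mpcr" & !is.na(panel$amplicon_bp)])
  gd <- sort(panel$amplicon_bp[panel$assay == "mqpcr" & !is.na(panel$amplicon_bp)])
  if (!identical(mt, sort(c(274L, 398L, 169L, 439L))) ||
      !identical(gd, sort(c(104L, 107L, 97L, 135L))))
    stop("assay panel amplicon lengths are inconsistent with the validated panel")
  panel
}

.parseCall <- function(value, file, line, column) {
  v <- trimws(as.character(value))
  if (v %in% c("+", "1", "TRUE")) return(TRUE)
  if (v %in% c("-", "0", "FALSE")) return(FALSE)
  stop("malformed call '", v, "' in ", file, " line ", line,
       " column '", column, "' (use +/- or 1/0)")
}

#' Parse declared compositions and PCR species calls
#'
#' Reads a declarations table (columns \code{sample_id},
#' \code{product_type}, one +/- column per species, optional \code{*_pct}
#' percent columns) and a calls table (columns \code{sample_id},
#' \code{assay} in \code{mpcr}/\code{mqpcr}, one +/- column per species) and
#' merges them into one record per sample. The chicken column of the
#' mitochondrial multiplex is the combined chicken/turkey call, so a
#' declared poultry content is satisfied by it. Species columns outside
#' pork/chicken/beef and any call value other than +/- (or 1/0) are
#' rejected, with the offending line reported.
#'
#' @param declarationsFile,callsFile CSV paths; defaults: the packaged
#'   transcriptions of the validation study's 27 retail products.
#' @return \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{product_type}, and logical columns \code{declared_*},
#'   \code{mpcr_*}, \code{mqpcr_*} for each species.
#' @examples
#' records <- parseSpeciesCalls()
#' records[records$sample_id == 3, ]
#' @export
parseSpeciesCalls <- function(declarationsFile = NULL, callsFile = NULL) {
  if (is.null(declarationsFile))
    declarationsFile <- system.file("extdata", "table1_declared.csv",
                                    package = "tagprint", mustWork = TRUE)
  if (is.null(callsFile))
    callsFile <- system.file("extdata", "table4_calls.csv",
                             package = "tagprint", mustWork = TRUE)
  decl <- utils::read.csv(declarationsFile, stringsAsFactors = FALSE)
  calls <- utils::read.csv(callsFile, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "product_type") %in% names(decl)))
    stop("declarations need columns sample_id and product_type")
  declSpecies <- setdiff(names(decl),
                         c("sample_id", "product_type",
                           grep("_pct$", names(decl), value = TRUE)))
  bad <- setdiff(declSpecies, .CALL_SPECIES)
  if (length(bad))
    stop("unknown species column(s) in declarations: ",
         paste(bad, collapse = ", "))
  if (nrow(calls)) {
    if (!all(c("sample_id", "assay") %in% names(calls)))
      stop("calls need columns sample_id and assay")
    callSpecies <- setdiff(names(calls), c("sample_id", "assay"))
    bad <- setdiff(callSpecies, .CALL_SPECIES)
    if (length(bad))
      stop("unknown species column(s) in calls: ", paste(bad, collapse = ", "))
    if (any(!calls$assay %in% c("mpcr", "mqpcr")))
      stop("assay must be 'mpcr' or 'mqpcr'")
  }
  out <- data.frame(sample_id = decl$sample_id,
                    product_type = decl$product_type,
                    stringsAsFactors = FALSE)
  for (sp in .CALL_SPECIES) {
    out[[paste0("declared_", sp)]] <- if (sp %in% declSpecies)
      vapply(seq_len(nrow(decl)), function(i)
        .parseCall(decl[[sp]][i], basename(declarationsFile), i + 1L, sp),
        logical(1))
    else FALSE
    for (assay in c("mpcr", "mqpcr")) {
      sub <- calls[calls$assay == assay, , drop = FALSE]
      idx <- match(out$sample_id, sub$sample_id)
      if (nrow(calls) && anyNA(idx))
        stop("missing ", assay, " calls for sample(s): ",
             paste(out$sample_id[is.na(idx)], collapse = ", "))
      out[[paste0(assay, "_", sp)]] <- if (nrow(calls) && sp %in% names(sub))
        vapply(idx, function(i)
          .parseCall(sub[[sp]][i], basename(callsFile),
                     which(calls$assay == assay)[i] + 1L, sp), logical(1))
      else FALSE
    }
  }
  if (!nrow(calls)) out <- out[0, , drop = FALSE]
  out
}

#' Check label compliance and mtDNA/gDNA concordance
#'
#' The genomic-DNA (real-time multiplex) calls are the authoritative basis:
#' a sample is label-compliant when that assay detects every declared
#' species and no undeclared one. The mitochondrial endpoint multiplex
#' serves only the concordance flag: a sample is mtDNA/gDNA-discrepant when
#' the two assays disagree for any species — the signature of fat-rich,
#' highly processed products where mitochondrial targets drop out.
#'
#' @param records \code{data.frame} from [parseSpeciesCalls()] (non-empty).
#' @return \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{product_type}, \code{label_compliant},
#'   \code{undeclared_species}, \code{missing_declared} (semicolon-joined
#'   lists, \code{""} when empty), \code{mt_gdna_discrepant}.
#' @examples
#' report <- checkCompliance(parseSpeciesCalls())
#' sum(report$label_compliant)      # 27
#' report$sample_id[report$mt_gdna_discrepant]
#' @export
checkCompliance <- function(records) {
  if (!nrow(records)) stop("no records to check")
  res <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    declared <- .CALL_SPECIES[vapply(.CALL_SPECIES, function(s)
      r[[paste0("declared_", s)]], logical(1))]
    detected <- .CALL_SPECIES[vapply(.CALL_SPECIES, function(s)
      r[[paste0("mqpcr_", s)]], logical(1))]
    undeclared <- setdiff(detected, declared)
    missing <- setdiff(declared, detected)
    discrepant <- any(vapply(.CALL_SPECIES, function(s)
      r[[paste0("mpcr_", s)]] != r[[paste0("mqpcr_", s)]], logical(1)))
    data.frame(sample_id = r$sample_id, product_type = r$product_type,
               label_compliant = length(undeclared) == 0 && length(missing) == 0,
               undeclared_species = paste(undeclared, collapse = ";"),
               missing_declared = paste(missing, collapse = ";"),
               mt_gdna_discrepant = discrepant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summarize a compliance report by product type
#'
#' @param report \code{data.frame} from [checkCompliance()] (may be empty).
#' @return \code{data.frame} with one row per product type:
#'   \code{product_type}, \code{n}, \code{compliant}, \code{non_compliant},
#'   \code{discrepant}.
#' @export
summarizeCompliance <- function(report) {
  if (!nrow(report))
    return(data.frame(product_type = character(0), n = integer(0),
                      compliant = integer(0), non_compliant = integer(0),
                      discrepant = integer(0), stringsAsFactors = FALSE))
  types <- sort(unique(report$product_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    sub <- report[report$product_type == tp, ]
    data.frame(product_type = tp, n = nrow(sub),
               compliant = sum(sub$label_compliant),
               non_compliant = sum(!sub$label_compliant),
               discrepant = sum(sub$mt_gdna_discrepant),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
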