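#' Gene signatures
#'
#' A gene signature is a named, ordered list of unique gene symbols: a marker
#' panel, a proliferation gene list, or a transcription-factor regulon. All
#' per-cell scoring in this package operates on these objects.
#'
#' @param name Single string naming the signature.
#' @param genes Character vector of gene symbols. Must be non-empty; duplicate
#'   symbols are removed (first occurrence kept) with a warning, so the stored
#'   gene list is always unique and ordered.
#'
#' @return An object of class `gene_signature`: a list with elements `name`
#'   and `genes`.
#' @export
#' @examples
#' gene_signature("myoepithelial", c("Krt17", "Krt14", "Krt5"))
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(genes) || length(genes) == 0L) {
    stop("signature '", name, "' must have at least one gene symbol", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    warning("signature '", name, "' contains duplicate symbols; keeping first occurrences",
            call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, " (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Built-in mammary epithelium and PPBC signature registry
#'
#' Returns the five gene lists the pipeline is built around, as shipped in the
#' package's `extdata/signatures.json`:
#'
#' * `AV` — luminal alveolar (milk-producing) markers: Mfge8, Trf, Csn3,
#'   Wfdc18, Ltf.
#' * `HS` — luminal hormone-sensing markers: Prlr, Pgr, Esr1, Cited1, Prom1.
#' * `ME` — myoepithelial markers: Krt17, Krt14, Krt5.
#' * `proliferation` — six cell-cycle genes whose combined feature sum defines
#'   the proliferation score: Cenpe, Ccna2, Ccnb2, Mcm6, Ccnf, Bud1.
#' * `regulon` — the 14-transcription-factor post-partum breast cancer (PPBC)
#'   regulon: Bclaf1, Cux1, E2f1, E2f4, Esr1, Foxm1, Gtf2b, Max, Myc, Nfya,
#'   Nr4a1, Nrf1, Smarca4, Taf1.
#'
#' The lists are shipped verbatim; in particular `Bud1` in the proliferation
#' list is kept as published even though `Bub1` may have been intended — symbol
#' misses against a matrix are reported at scoring time, never auto-corrected.
#' Note that Esr1 legitimately appears in both the HS marker panel and the
#' regulon.
#'
#' @return Named list of [gene_signature] objects.
#' @export
#' @examples
#' length(ppbc_signatures()$regulon)  # 14
ppbc_signatures <- function() {
  path <- system.file("extdata", "signatures.json", package = "ppbclike",
                      mustWork = TRUE)
  read_signature_registry(path)
}

#' Read and write a signature registry (JSON)
#'
#' The registry format is a JSON object mapping signature name to an array of
#' gene symbols.
#'
#' @param path Path to a JSON file.
#' @return `read_signature_registry()` returns a named list of
#'   [gene_signature] objects; `write_signature_registry()` returns `path`
#'   invisibly.
#' @export
read_signature_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("signature registry must be a JSON object of name -> gene array", call. = FALSE)
  }
  out <- lapply(names(raw), function(nm) gene_signature(nm, as.character(raw[[nm]])))
  names(out) <- names(raw)
  out
}

#' @rdname read_signature_registry
#' @param registry Named list of [gene_signature] objects (or bare character
#'   vectors, which are converted).
#' @export
write_signature_registry <- function(registry, path) {
  stopifnot(is.list(registry), !is.null(names(registry)))
  lst <- lapply(registry, function(s) if (inherits(s, "gene_signature")) s$genes else as.character(s))
  jsonlite::write_json(lst, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Normalize gene symbols to the mouse convention
#'
#' Mouse gene symbols are conventionally written with an initial capital and
#' the remainder lower-case ("TRP53" -> "Trp53", "e2f1" -> "E2f1"). Matching
#' against a matrix is case-sensitive after this normalization; apply it to
#' signature lists, not to arbitrary matrix symbols (Riken-style identifiers
#' would be mangled).
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_mouse_symbols(c("TRP53", "krt14"))
normalize_mouse_symbols <- function(x) {
  stopifnot(is.character(x))
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}
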