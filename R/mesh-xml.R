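#' Import MeSH descriptor XML
#'
#' Reads a MeSH descriptor export (`DescriptorRecordSet` XML as distributed
#' by the US National Library of Medicine) and maps it onto the native
#' record format: `DescriptorUI` -> id, `DescriptorName` -> label, entry
#' `TermList` terms -> synonyms, `TreeNumberList` -> tree addresses.
#' Descriptors without any tree number are dropped (they cannot take part
#' in distance scoring). Requires the xml2 package.
#'
#' @param path path to a descriptor XML file.
#' @return a `crt_vocabulary`, see [load_vocabulary()].
#' @export
read_mesh_xml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    abort("read_mesh_xml requires the xml2 package")
  if (!file.exists(path)) abort("file not found: ", path,
                                class = "crtool_io_error")
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  out <- list()
  for (r in recs) {
    ui <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorUI"))
    label <- xml2::xml_text(
      xml2::xml_find_first(r, "./DescriptorName/String"))
    trees <- xml2::xml_text(
      xml2::xml_find_all(r, "./TreeNumberList/TreeNumber"))
    if (length(trees) == 0L) next
    terms <- xml2::xml_text(
      xml2::xml_find_all(r, ".//TermList/Term/String"))
    syns <- setdiff(unique(terms), label)
    out[[length(out) + 1L]] <- list(
      id = ui, label = label, synonyms = syns, tree_addresses = trees)
  }
  if (length(out) == 0L) abort("no descriptor with tree numbers found in ", path)
  load_vocabulary(out)
}
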