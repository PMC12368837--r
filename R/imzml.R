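# Minimal continuous-mode imzML I/O: an XML index file plus a binary .ibd
# container holding one shared m/z array and one intensity array per pixel
# (64-bit little-endian floats). Covers what this package produces; it is
# not a general-purpose imzML implementation.

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write an image grid to continuous-mode imzML
#'
#' The shared m/z axis is the bin-centre axis of the grid; each pixel's
#' normalized binned intensities become one spectrum. Positions are 1-based
#' (x = column, y = row).
#'
#' @param grid An [reconstruct_image()] grid.
#' @param path Output path (`.imzML`; the `.ibd` sibling is written next to
#'   it).
#' @return The imzML path, invisibly.
#' @export
write_imzml <- function(grid, path) {
  p <- imzml_paths(path)
  mz <- grid$bin_lo + grid$bin_width / 2
  n_mz <- length(mz)
  n_pix <- nrow(grid$values)
  uuid <- as.raw(c(0x4c, 0x41, 0x52, 0x45, 0x49, 0x4d, 0x53, 0x00,
                   sample.int(256, 8, replace = TRUE) - 1L))

  con <- file(p$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  writeBin(as.numeric(mz), con, size = 8, endian = "little")
  for (i in seq_len(n_pix)) {
    writeBin(as.numeric(grid$values[i, ]), con, size = 8, endian = "little")
  }

  mz_offset <- 16
  int_offsets <- mz_offset + 8 * n_mz + 8 * n_mz * (seq_len(n_pix) - 1)
  rowv <- rep(seq_len(grid$rows), each = grid$cols)
  colv <- rep(seq_len(grid$cols), times = grid$rows)

  spectra <- vapply(seq_len(n_pix), function(i) {
    sprintf(paste0(
      '      <spectrum index="%d" defaultArrayLength="%d">\n',
      '        <scanList count="1"><scan>\n',
      '          <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '          <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '        </scan></scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>'),
      i - 1, n_mz, colv[i], rowv[i], mz_offset, n_mz,
      int_offsets[i], n_mz)
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <fileDescription><fileContent>\n',
    '    <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    sprintf('    <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
            paste(format(uuid), collapse = "")),
    '  </fileContent></fileDescription>\n',
    sprintf('  <scanSettingsList count="1"><scanSettings id="scan1">\n    <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n    <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n    <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>\n  </scanSettings></scanSettingsList>\n',
            grid$cols, grid$rows, grid$pixel_size),
    sprintf('  <run id="r1">\n    <spectrumList count="%d">\n', n_pix),
    paste(spectra, collapse = "\n"), "\n",
    '    </spectrumList>\n  </run>\n</mzML>\n'
  )
  writeLines(xml, p$xml)
  invisible(p$xml)
}

#' Read continuous-mode imzML
#'
#' @param path Path to an `.imzML` file with its `.ibd` sibling.
#' @return A list: `values` (pixels x mz matrix in row-major pixel order),
#'   `mz`, `coords` (tibble of x/y positions), `rows`, `cols`,
#'   `pixel_size`.
#' @export
read_imzml <- function(path) {
  p <- imzml_paths(path)
  doc <- xml2::read_xml(p$xml)
  xml2::xml_ns_strip(doc)
  rows <- as.integer(xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000043']"), "value"))
  cols <- as.integer(xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000042']"), "value"))
  psize <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000046']"), "value"))
  specs <- xml2::xml_find_all(doc, "//spectrum")
  get_num <- function(node, acc) {
    as.numeric(xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc)),
      "value"))
  }
  xs <- vapply(specs, get_num, numeric(1), "IMS:1000050")
  ys <- vapply(specs, get_num, numeric(1), "IMS:1000051")
  arrays <- lapply(specs, function(sp) {
    bda <- xml2::xml_find_all(sp, ".//binaryDataArray")
    lapply(bda, function(b) {
      list(offset = get_num(b, "IMS:1000102"),
           length = get_num(b, "IMS:1000103"),
           is_mz = length(xml2::xml_find_all(
             b, ".//cvParam[@accession='MS:1000514']")) > 0)
    })
  })
  con <- file(p$ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_at <- function(offset, n) {
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = n, size = 8, endian = "little")
  }
  mz_info <- Filter(function(a) a$is_mz, arrays[[1]])[[1]]
  mz <- read_at(mz_info$offset, mz_info$length)
  values <- t(vapply(arrays, function(a) {
    ii <- Filter(function(b) !b$is_mz, a)[[1]]
    read_at(ii$offset, ii$length)
  }, numeric(length(mz))))
  ord <- order(ys, xs)
  list(values = values[ord, , drop = FALSE], mz = mz,
       coords = tibble::tibble(x = xs[ord], y = ys[ord]),
       rows = rows, cols = cols, pixel_size = psize)
}
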