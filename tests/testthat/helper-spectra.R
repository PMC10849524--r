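# Helpers shared across spectral tests: build an MS2 peak list holding an
# exact (optionally mixed) fragment ladder, and write a minimal mzML file
# so the mzR reading path can be exercised without binary fixtures.

# Merged fragment spectrum of a weighted proteoform mixture (weights are
# within-class fractions). Noise-free unless a noise vector is supplied.
mixture_ms2 <- function(states_list, weights, schema,
                        precursor_mz, precursor_z,
                        coverage = 1, noise_cv = 0, scan_id = "mix") {
  bb <- histone_backbone(schema$backbone)
  mass <- unlist(lapply(states_list, function(st) {
    fl <- etd_fragments(bb, st, scale = "monoisotopic")
    c(fl$c, fl$z)
  }))
  nfrag <- length(mass) / length(states_list)
  w <- rep(weights, each = nfrag)
  merged <- histoform:::.merge_observed(mass, w, 10)
  if (coverage < 1) {
    keep <- stats::runif(nrow(merged)) <= coverage
    merged <- merged[keep, , drop = FALSE]
  }
  inten <- merged$intensity * 1e5
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    inten <- inten * exp(stats::rnorm(length(inten), -sigma^2 / 2, sigma))
  }
  spectrum_peaklist("MS2", merged$mass + proton_mass(), inten,
                    precursor = list(mz = precursor_mz, charge = precursor_z,
                                     window_da = 3.4),
                    scan_id = scan_id)
}

# Minimal mzML writer (64-bit float, no compression) for test fixtures.
write_test_mzml <- function(spectra, path) {
  enc <- function(x) {
    gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                 size = 8, endian = "little")))
  }
  spec_xml <- function(sp, index) {
    n <- nrow(sp$peaks)
    prec <- ""
    if (!is.null(sp$precursor)) {
      prec <- sprintf('<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>
        <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
        <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>
      </selectedIon></selectedIonList><activation>
        <cvParam cvRef="MS" accession="MS:1000598" name="electron transfer dissociation" value=""/>
      </activation></precursor></precursorList>',
      sp$precursor$mz, as.integer(sp$precursor$charge))
    }
    b_mz <- enc(sp$peaks$mz); b_in <- enc(sp$peaks$intensity)
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>
      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>%s
      <binaryDataArrayList count="2">
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
          <binary>%s</binary>
        </binaryDataArray>
        <binaryDataArray encodedLength="%d">
          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
          <binary>%s</binary>
        </binaryDataArray>
      </binaryDataArrayList>
    </spectrum>', index, index + 1L, n,
    if (sp$level == "MS2") 2L else 1L, prec,
    nchar(b_mz), b_mz, nchar(b_in), b_in)
  }
  body <- paste(vapply(seq_along(spectra),
                       function(i) spec_xml(spectra[[i]], i - 1L),
                       character(1)), collapse = "\n")
  doc <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>
  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>
  <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp">
%s
    </spectrumList>
  </run>
</mzML>', length(spectra), body)
  writeLines(doc, path)
  invisible(path)
}

# Small abundance table builder: named abundances -> one-sample table.
toy_table <- function(abund, family = "H4", sample = "s1",
                      condition = "TN", tissue = "BAT") {
  tibble::tibble(family = family, notation = names(abund), sample = sample,
                 condition = condition, tissue = tissue,
                 abundance = unname(abund))
}
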