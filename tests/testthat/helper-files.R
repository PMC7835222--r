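# Write lines to a session tempfile and return its path.
withr_tempfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
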