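# Tiny standalone SVG emitter: the plots this package writes (dot plots,
# correction-vector quivers) are simple enough that hand-written elements
# keep the output dependency-free and diffable.
svg_write <- function(elements, path, width, height) {
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                     round(width), round(height), round(width), round(height)),
             elements,
             "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
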