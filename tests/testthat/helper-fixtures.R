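# Deterministic trial tables with fully specified responses, for testing the
# metric independently of the generative model. Objects appear in a fixed
# within-block rotation; response_fn(height, is_outlier, block) gives the
# spring-length response.
build_table <- function(spec, response_fn, id = "T01") {
  rows <- list()
  trial <- 0L
  fam <- which(!spec$objects$is_outlier)
  out <- which(spec$objects$is_outlier)
  for (b in seq_len(nrow(spec$blocks))) {
    objs <- c(fam, rep(out, spec$blocks$n_outlier[b]))
    for (o in objs) {
      trial <- trial + 1L
      rows[[trial]] <- data.frame(
        participant = id,
        condition = spec$name,
        trial = trial,
        block = spec$blocks$block[b],
        object_height_cm = spec$objects$height_cm[o],
        object_mass_g = spec$objects$mass_g[o],
        is_outlier = spec$objects$is_outlier[o],
        response_cm = NA_real_
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$response_cm <- mapply(response_fn, tab$object_height_cm, tab$is_outlier,
                            tab$block)
  tab
}

# A noiseless responder whose family responses lie exactly on a line and
# whose outlier responses are a constant.
line_responder <- function(intercept, slope, outlier_response) {
  function(h, is_out, block) {
    if (is_out) outlier_response else intercept + slope * h
  }
}
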