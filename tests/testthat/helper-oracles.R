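# Independent recount-and-classify oracle for a single linear position.
classify_oracle <- function(counts, ref_base, min_depth = 10, min_freq = 0.30,
                            mixed_upper = 0.70) {
  depth <- sum(counts)
  if (depth < min_depth) return(NULL)
  freq <- counts / depth
  observed <- names(counts)[freq >= min_freq]
  non_ref <- setdiff(observed, ref_base)
  if (length(non_ref) == 0) return(NULL)
  alt <- non_ref[which.max(freq[non_ref])]
  if (freq[alt] > mixed_upper) return(list(type = "substitution", call = alt))
  if (length(observed) >= 2 && all(freq[observed] <= mixed_upper))
    return(list(type = "mixed", call = iupac_code(observed)))
  NULL
}

# Independent brute-force PMD evaluator: scalar loop over positions, written
# separately from the package's vectorized implementation.
pmd_oracle <- function(ref_str, obs_str, quals, model, mode = "both") {
  rc <- strsplit(ref_str, "")[[1]]
  oc <- strsplit(obs_str, "")[[1]]
  n <- length(rc)
  total <- 0
  for (i in seq_len(n)) {
    e <- 10^(-quals[i] / 10)
    if (rc[i] == "C") {
      z <- i - 1
      d <- if (mode %in% c("both", "five"))
        model$p_background + model$p_max * model$lambda^z else model$p_background
      if (oc[i] == "T")
        total <- total + log((d * (1 - e) + (1 - d) * e / 3) / (e / 3))
      else if (oc[i] == "C")
        total <- total + log(((1 - d) * (1 - e) + d * e / 3) / (1 - e))
    } else if (rc[i] == "G") {
      z <- n - i
      d <- if (mode %in% c("both", "three"))
        model$p_background + model$p_max * model$lambda^z else model$p_background
      if (oc[i] == "A")
        total <- total + log((d * (1 - e) + (1 - d) * e / 3) / (e / 3))
      else if (oc[i] == "G")
        total <- total + log(((1 - d) * (1 - e) + d * e / 3) / (1 - e))
    }
  }
  total
}
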