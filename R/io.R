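#' Write an hourly size-distribution series to CSV (long format)
#'
#' Columns `hour`, `class_index`, `count`; grid parameters travel in a
#' three-line header comment (`# v_min=`, `# p=`, `# m=`) so the file is
#' self-describing.
#'
#' @param obs a [size_distribution_series()].
#' @param file path.
#' @export
write_size_distribution_csv <- function(obs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  g <- obs$grid
  writeLines(c(sprintf("# v_min=%g", g$v_min), sprintf("# p=%d", g$p),
               sprintf("# m=%d", g$m)), con)
  long <- data.frame(hour = rep(obs$hours, each = g$m),
                     class_index = rep(seq_len(g$m), nrow(obs$counts)),
                     count = as.integer(t(obs$counts)))
  utils::write.csv(long, con, row.names = FALSE)
}

#' Read an hourly size-distribution series written by
#' [write_size_distribution_csv()]
#' @param file path.
#' @return a [size_distribution_series()].
#' @export
read_size_distribution_csv <- function(file) {
  hdr <- readLines(file, n = 3)
  val <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, "="), "", line))
  }
  grid <- size_grid(val("v_min"), as.integer(val("p")), as.integer(val("m")))
  long <- utils::read.csv(file, comment.char = "#")
  hours <- sort(unique(long$hour))
  counts <- matrix(NA_integer_, length(hours), grid$m)
  for (i in seq_along(hours)) {
    rows <- long[long$hour == hours[i], ]
    counts[i, rows$class_index] <- rows$count
  }
  size_distribution_series(counts, grid, hours = hours)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
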