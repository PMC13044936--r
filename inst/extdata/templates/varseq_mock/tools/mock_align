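#!/bin/sh
# toy aligner: assigns each read a deterministic reference position
IDX=""; IN=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -x) IDX="$2"; shift 2 ;;
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IDX" ] && [ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_align -x idx -i reads -o out" >&2; exit 2; }
[ -f "$IDX" ] || { echo "mock_align: missing index: $IDX" >&2; exit 1; }
[ -f "$IN" ] || { echo "mock_align: no such file: $IN" >&2; exit 1; }
awk -v OFS='\t' '{pos = (NR * 97 + length($2)) % 1000 + 1; print $1, "ref1", pos, $2}' "$IN" > "$OUT"
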