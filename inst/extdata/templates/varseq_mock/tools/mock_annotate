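#!/bin/sh
# toy functional annotator: adds a deterministic consequence column
IN=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_annotate -i in -o out" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_annotate: no such file: $IN" >&2; exit 1; }
awk -F'\t' -v OFS='\t' '
  NR == 1 { sub(/^#/, "", $1); print $0, "CONSEQUENCE"; next }
  {
    c = ($6 >= 70) ? "stop_gained" : (($6 % 2 == 1) ? "missense" : "synonymous")
    print $0, c
  }' "$IN" > "$OUT"
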