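#!/bin/sh
# toy duplicate marker: keeps the first alignment at each position
IN=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_dedup -i in -o out" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_dedup: no such file: $IN" >&2; exit 1; }
awk -F'\t' '!seen[$3]++' "$IN" > "$OUT"
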