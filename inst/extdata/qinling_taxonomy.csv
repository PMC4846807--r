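species,genus,family
Betula albosinensis,Betula,Betulaceae
Betula platyphylla,Betula,Betulaceae
Betula luminifera,Betula,Betulaceae
Betula utilis,Betula,Betulaceae
Carpinus turczaninowii,Carpinus,Betulaceae
Corylus chinensis,Corylus,Betulaceae
Ostrya japonica,Ostrya,Betulaceae
Pinus armandii,Pinus,Pinaceae
Pinus tabuliformis,Pinus,Pinaceae
Abies fargesii,Abies,Pinaceae
Tsuga chinensis,Tsuga,Pinaceae
Larix chinensis,Larix,Pinaceae
Picea wilsonii,Picea,Pinaceae
Quercus aliena var. acutiserrata,Quercus,Fagaceae
Quercus variabilis,Quercus,Fagaceae
Quercus spinosa,Quercus,Fagaceae
Castanea seguinii,Castanea,Fagaceae
Acer davidii,Acer,Aceraceae
Acer caesium,Acer,Aceraceae
Acer grosseri,Acer,Aceraceae
Acer maximowiczii,Acer,Aceraceae
Acer tsinglingense,Acer,Aceraceae
Acer caudatum,Acer,Aceraceae
Toxicodendron vernicifluum,Toxicodendron,Anacardiaceae
Rhus potaninii,Rhus,Anacardiaceae
Sorbus folgneri,Sorbus,Rosaceae
Sorbus koehneana,Sorbus,Rosaceae
Cerasus polytricha,Cerasus,Rosaceae
Crataegus wilsonii,Crataegus,Rosaceae
Malus kansuensis,Malus,Rosaceae
Prunus salicina,Prunus,Rosaceae
Lindera obtusiloba,Lindera,Lauraceae
Litsea tsinlingensis,Litsea,Lauraceae
Populus davidiana,Populus,Salicaceae
Populus purdomii,Populus,Salicaceae
Salix wallichiana,Salix,Salicaceae
Juglans cathayensis,Juglans,Juglandaceae
Pterocarya stenoptera,Pterocarya,Juglandaceae
Cornus controversa,Cornus,Cornaceae
Cornus kousa,Cornus,Cornaceae
Tilia chinensis,Tilia,Tiliaceae
Tilia paucicostata,Tilia,Tiliaceae
Kalopanax septemlobus,Kalopanax,Araliaceae
Aralia chinensis,Aralia,Araliaceae
Catalpa fargesii,Catalpa,Bignoniaceae
Fraxinus chinensis,Fraxinus,Oleaceae
Ulmus pumila,Ulmus,Ulmaceae
Celtis sinensis,Celtis,Ulmaceae
Rhododendron purdomii,Rhododendron,Ericaceae
Viburnum betulifolium,Viburnum,Caprifoliaceae
Euonymus phellomanus,Euonymus,Celastraceae
Meliosma cuneifolia,Meliosma,Sabiaceae
Dipteronia sinensis,Dipteronia,Aceraceae
Pterostyrax hispidus,Pterostyrax,Styracaceae
Schima superba,Schima,Theaceae
Albizia kalkora,Albizia,Fabaceae
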